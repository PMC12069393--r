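[PAD]
[UNK]
[CLS]
[SEP]
[MASK]
:
,
.
-
%
(
)
;
_
/
0
1
2
3
4
5
6
7
8
9
##0
##1
##2
##3
##4
##5
##6
##7
##8
##9
##.
a
b
c
d
e
f
g
h
i
j
k
l
m
n
o
p
q
r
s
t
u
v
w
x
y
z
##a
##b
##c
##d
##e
##f
##g
##h
##i
##j
##k
##l
##m
##n
##o
##p
##q
##r
##s
##t
##u
##v
##w
##x
##y
##z
hr
pdur
qrsdur
tdur
cycledur
qrsarea
qrsperim
anglepqr
angleqrs
anglerst
angleponpq
anglesttoff
pqint
ptint
qrint
qtint
rsint
stint
pqslope
qrslope
rsslope
stslope
dponppeak
dponq
dponr
dpons
dpontpeak
dppeakq
dppeakr
dppeaks
dppeaktpeak
dqr
dqs
dqtpeak
drs
drtpeak
dstpeak
dponpoff
dpoffq
dstoff
dtontoff
rrmean
ppmean
qrtoqsdur
rstoqsdur
ibim
sdrr
ibisd
nn50
pnn50
sdsd
rmssd
rrtot
nntot
arr
aff
chf
nsr
label
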