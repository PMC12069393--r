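# Feature-to-text serialization, label encoding and WordPiece-style
# tokenization.  The default vocabulary is a frozen uncased WordPiece-style
# vocab shipped with the package (special tokens, punctuation, digits and
# digit continuations, letters, the registry feature names and the class
# names); any vocabulary file with one token per line can be substituted.

#' Serialize selected features of one row to text
#'
#' Produces `"name: value, name: value, ..."` with fixed-point values at
#' `precision` decimals in selection order.  Rounding is R's default
#' round-half-even.
#'
#' @param vector Named numeric vector (a feature-table row).
#' @param selected Ordered character vector of selected registry names.
#' @param precision Decimal places (default 3).
#' @return A single string.
#' @export
serialize_features <- function(vector, selected, precision = 3) {
  if (length(selected) == 0) stop("empty selection list")
  reg <- feature_registry()$name
  bad <- setdiff(selected, reg)
  if (length(bad)) stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  vals <- vector[selected]
  if (anyNA(vals)) {
    stop("missing value(s) for: ",
         paste(selected[is.na(vals)], collapse = ", "),
         " (serialization requires complete rows; impute first)")
  }
  paste(sprintf("%s: %.*f", selected, precision, as.numeric(vals)),
        collapse = ", ")
}

#' Encode class labels as integer ids
#'
#' Ids are assigned in lexicographic class-name order (AFF=0, ARR=1,
#' CHF=2, NSR=3 for the four standard classes).
#'
#' @param labels Character vector of class names.
#' @return Object of class `label_encoder`: `classes` (ordered), and the
#'   mapping is `id = match(label, classes) - 1`.
#' @export
encode_labels <- function(labels) {
  classes <- sort(unique(as.character(labels)))
  structure(list(classes = classes), class = "label_encoder")
}

#' @rdname encode_labels
#' @param encoder A `label_encoder`.
#' @export
label_to_id <- function(encoder, labels) {
  ids <- match(as.character(labels), encoder$classes) - 1L
  if (anyNA(ids)) {
    stop("unseen label(s): ",
         paste(unique(labels[is.na(ids)]), collapse = ", "))
  }
  ids
}

#' @rdname encode_labels
#' @param ids Integer ids in `[0, K)`.
#' @export
id_to_label <- function(encoder, ids) {
  if (any(ids < 0 | ids >= length(encoder$classes))) stop("id out of range")
  encoder$classes[ids + 1L]
}

#' Save / load a label encoder as JSON
#' @inheritParams label_to_id
#' @param path JSON path.
#' @export
write_label_encoder <- function(encoder, path) {
  jsonlite::write_json(list(classes = encoder$classes), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_label_encoder
#' @export
read_label_encoder <- function(path) {
  structure(list(classes = unlist(jsonlite::read_json(path)$classes)),
            class = "label_encoder")
}

#' Load a tokenizer vocabulary
#'
#' @param path Vocabulary file, one token per line.  Default: the frozen
#'   vocabulary shipped in `inst/extdata/vocab.txt`.
#' @return Object of class `wp_vocab` (token vector + lookup).
#' @export
load_vocab <- function(path = system.file("extdata", "vocab.txt",
                                          package = "cvdmix")) {
  tokens <- readLines(path, warn = FALSE)
  tokens <- tokens[nzchar(tokens)]
  if (anyDuplicated(tokens)) stop("vocabulary contains duplicate tokens")
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(tokens)) assign(tokens[i], i - 1L, envir = lookup)
  needed <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]")
  if (!all(needed %in% tokens)) {
    stop("vocabulary must contain the special tokens ",
         paste(needed, collapse = " "))
  }
  structure(list(tokens = tokens, lookup = lookup, size = length(tokens)),
            class = "wp_vocab")
}

vocab_id <- function(vocab, token) {
  get0(token, envir = vocab$lookup, ifnotfound = NA_integer_)
}

# basic tokenization: lowercase, split punctuation into standalone tokens
basic_tokenize <- function(text) {
  text <- tolower(text)
  text <- gsub("([[:punct:]])", " \\1 ", text)
  words <- strsplit(trimws(gsub("[[:space:]]+", " ", text)), " ",
                    fixed = TRUE)[[1]]
  words[nzchar(words)]
}

wordpiece_word <- function(vocab, word) {
  n <- nchar(word)
  out <- character(0)
  start <- 1L
  while (start <= n) {
    found <- NA_character_
    for (end in n:start) {
      piece <- substr(word, start, end)
      if (start > 1L) piece <- paste0("##", piece)
      if (!is.na(vocab_id(vocab, piece))) { found <- piece; break }
    }
    if (is.na(found)) return("[UNK]")
    out <- c(out, found)
    start <- start + nchar(sub("^##", "", found))
  }
  out
}

#' Tokenize a serialized feature string
#'
#' Uncased WordPiece-style subword tokenization with `[CLS]`/`[SEP]`
#' wrapping, right-padding with `[PAD]` to `max_len`, and silent (counted)
#' truncation beyond it.  Deterministic for a frozen vocabulary.
#'
#' @param text Non-empty string.
#' @param vocab A [load_vocab()] vocabulary.
#' @param max_len Sequence length (default 128).
#' @return Object of class `tokenized_sample`: `tokens`, `token_ids`
#'   (length `max_len`), `attention_mask`, `truncated` count, and `text`.
#' @export
tokenize <- function(text, vocab = load_vocab(), max_len = 128) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("text must be a non-empty string")
  }
  pieces <- unlist(lapply(basic_tokenize(text), wordpiece_word, vocab = vocab))
  truncated <- max(0L, length(pieces) - (max_len - 2L))
  if (truncated > 0) pieces <- pieces[seq_len(max_len - 2L)]
  toks <- c("[CLS]", pieces, "[SEP]")
  ids <- vapply(toks, vocab_id, integer(1), vocab = vocab)
  pad_n <- max_len - length(ids)
  mask <- c(rep(1L, length(ids)), rep(0L, pad_n))
  ids <- c(ids, rep(vocab_id(vocab, "[PAD]"), pad_n))
  structure(list(text = text, tokens = toks,
                 token_ids = unname(as.integer(ids)),
                 attention_mask = mask, truncated = truncated,
                 label_id = NA_integer_),
            class = "tokenized_sample")
}

#' Recover text from tokens (up to whitespace normalization)
#'
#' @param sample A `tokenized_sample` (or character vector of tokens).
#' @return String with `##` continuations merged and specials dropped.
#' @export
detokenize <- function(sample) {
  toks <- if (inherits(sample, "tokenized_sample")) sample$tokens else sample
  toks <- toks[!toks %in% c("[PAD]", "[CLS]", "[SEP]", "[MASK]")]
  out <- ""
  for (tk in toks) {
    if (startsWith(tk, "##")) {
      out <- paste0(out, sub("^##", "", tk))
    } else {
      out <- if (nzchar(out)) paste(out, tk) else tk
    }
  }
  # re-attach punctuation the basic tokenizer split off
  out <- gsub("(\\d) \\. (\\d)", "\\1.\\2", out)
  out <- gsub(" ([.,:;%)])", "\\1", out)
  out <- gsub("\\( ", "(", out)
  out
}

#' Tokenize a serialized corpus
#'
#' @param texts Character vector of serialized rows.
#' @param labels Class labels aligned with `texts`.
#' @param encoder A `label_encoder` (built from `labels` if NULL).
#' @param vocab,max_len Passed to [tokenize()].
#' @return List with `samples` (list of `tokenized_sample` with
#'   `label_id` set), `encoder`, `vocab`, `n_truncated`.
#' @export
tokenize_corpus <- function(texts, labels, encoder = NULL,
                            vocab = load_vocab(), max_len = 128) {
  stopifnot(length(texts) == length(labels))
  if (is.null(encoder)) encoder <- encode_labels(labels)
  ids <- label_to_id(encoder, labels)
  samples <- lapply(seq_along(texts), function(i) {
    s <- tokenize(texts[i], vocab, max_len)
    s$label_id <- ids[i]
    s
  })
  n_trunc <- sum(vapply(samples, function(s) s$truncated > 0, logical(1)))
  if (n_trunc > 0) cvd_log("tokenize_corpus: %d sample(s) truncated", n_trunc)
  list(samples = samples, encoder = encoder, vocab = vocab,
       n_truncated = n_trunc)
}
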