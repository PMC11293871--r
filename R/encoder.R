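#' Encoder contract
#'
#' A classifier backbone is anything that maps texts to fixed-length
#' context vectors (the role played by the `[CLS]` embedding of a
#' transformer's last hidden layer). An encoder is a list with fields
#' `name`, `dim` and is dispatched through [encode_text()]; it must be
#' deterministic given its configuration and seed. The reference
#' implementation is a seeded feature-hashing bag-of-tokens encoder,
#' [hashed_encoder()]; transformer backbones can be plugged in via
#' [custom_encoder()] without touching the rest of the pipeline.
#'
#' @param name Encoder name (used in manifests).
#' @param dim Output dimension.
#' @param encode_fn Function `character vector -> n x dim matrix`.
#' @return An object of class `dti_encoder`.
#' @export
custom_encoder <- function(name, dim, encode_fn) {
  structure(list(name = name, dim = as.integer(dim), encode_fn = encode_fn),
            class = c("dti_custom_encoder", "dti_encoder"))
}

#' Seeded feature-hashing bag-of-tokens encoder
#'
#' Tokenizes on whitespace (lowercasing; marker and separator tokens are
#' preserved as tokens), hashes each token with a seeded multiplicative
#' rolling hash into one of `dim` signed buckets, accumulates counts and
#' L2-normalizes each row. Fully deterministic given `dim` and `seed`,
#' vocabulary-free, and fast enough for CPU-scale experiments.
#'
#' @param dim Number of hash buckets (output dimension), default 512.
#' @param seed Integer mixed into the hash, so different seeds give
#'   different (but reproducible) feature spaces.
#' @return An object of class `dti_encoder`.
#' @export
hashed_encoder <- function(dim = 512, seed = 0) {
  structure(list(name = sprintf("hashed:%d", dim), dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = c("dti_hashed_encoder", "dti_encoder"))
}

#' Encode texts into context vectors
#'
#' @param encoder A `dti_encoder`.
#' @param texts Character vector.
#' @return Numeric matrix with `length(texts)` rows and `encoder$dim`
#'   columns.
#' @export
encode_text <- function(encoder, texts) UseMethod("encode_text")

#' @export
encode_text.dti_custom_encoder <- function(encoder, texts) {
  out <- encoder$encode_fn(texts)
  if (!is.matrix(out) || ncol(out) != encoder$dim || nrow(out) != length(texts)) {
    abort(sprintf("Encoder '%s' returned a malformed matrix", encoder$name))
  }
  out
}

#' @export
encode_text.dti_hashed_encoder <- function(encoder, texts) {
  if (any(!nzchar(texts))) abort("Cannot encode empty instance text")
  token_lists <- strsplit(tolower(texts), "[ \t\n]+")
  vocab <- unique(unlist(token_lists))
  h <- vapply(vocab, hash_token, numeric(1), seed = encoder$seed)
  bucket <- (h %% encoder$dim) + 1
  sign <- ifelse(((h * 7919 + 13) %% 16777216) %% 2 == 0, 1, -1)
  X <- matrix(0, nrow = length(texts), ncol = encoder$dim)
  for (i in seq_along(token_lists)) {
    idx <- match(token_lists[[i]], vocab)
    for (j in idx) X[i, bucket[j]] <- X[i, bucket[j]] + sign[j]
  }
  norms <- sqrt(rowSums(X^2))
  norms[norms == 0] <- 1
  X / norms
}

# 31-multiplier rolling hash over UTF-8 code points, mod 2^24 (kept
# exact in doubles), seeded by an additive offset.
hash_token <- function(token, seed) {
  h <- (seed * 2654435 + 99991) %% 16777216
  for (c in utf8ToInt(token)) h <- (h * 31 + c) %% 16777216
  h
}
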