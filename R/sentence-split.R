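# Deterministic, dependency-free sentence boundary detection shared by
# first_sentence() and split_sentences(). A boundary is a run of
# [.?!] followed by whitespace and then an uppercase letter or a digit,
# unless the token ending at the punctuation is a known abbreviation.

sentence_abbreviations <- function() {
  c(
    "e.g.", "i.e.", "cf.", "vs.", "ca.", "approx.", "et al.", "al.",
    "Dr.", "Prof.", "Fig.", "Figs.", "Eq.", "Ref.", "No.", "St."
  )
}

# Positions (1-based, in characters) of the last punctuation character of
# each sentence boundary within `text`.
sentence_boundary_positions <- function(text) {
  m <- gregexpr("[.?!]+(?=[ \t\n]+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  abbr <- sentence_abbreviations()
  keep <- vapply(ends, function(pos) {
    prefix <- substr(text, 1L, pos)
    # token ending at pos: trailing non-space run
    tok <- sub(".*[ \t\n]", "", prefix)
    !(tok %in% abbr)
  }, logical(1))
  ends[keep]
}

# Split `text` into trimmed sentence spans, returned as a tibble of
# 0-based half-open [start, end) intervals relative to `text` (offset 0).
split_text_spans <- function(text) {
  nchar_t <- nchar(text)
  if (nchar_t == 0) return(tibble(start = integer(), end = integer()))
  bounds <- sentence_boundary_positions(text)
  starts1 <- c(1L, bounds + 1L)         # 1-based candidate starts
  ends1 <- c(bounds, nchar_t)           # 1-based inclusive ends
  spans <- purrr::map2(starts1, ends1, function(s, e) {
    seg <- substr(text, s, e)
    lead <- nchar(seg) - nchar(sub("^[ \t\n]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[ \t\n]+$", "", seg))
    s2 <- s + lead
    e2 <- e - trail
    if (s2 > e2) NULL else c(s2, e2)
  })
  spans <- spans[!vapply(spans, is.null, logical(1))]
  tibble(
    start = vapply(spans, function(p) p[1] - 1L, integer(1)),
    end = vapply(spans, function(p) p[2], integer(1))
  )
}
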