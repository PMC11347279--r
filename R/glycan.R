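#' Parse a condensed glycan composition string
#'
#' Compositions like `"Glc3Man9GlcNAc2"` — the core N-glycan attached to
#' N598 of ER-resident hERG — are a concatenation of monosaccharide
#' tokens each followed by an optional count (omitted count = 1).
#' Tokens are matched greedily against a fixed vocabulary, longest
#' first, so `GlcNAc` is never mis-read as `Glc` + `NAc`.
#'
#' @param composition composition string.
#' @return list with `counts` (named integer vector, parse order) and
#'   `total` (sum of counts).
#' @examples
#' parse_glycan_composition("Glc3Man9GlcNAc2")$total  # 14
#' @export
parse_glycan_composition <- function(composition) {
  stopifnot(is.character(composition), length(composition) == 1L)
  vocab <- c("GlcNAc", "GalNAc", "ManNAc", "NeuAc", "NeuGc", "GlcA",
             "GalA", "IdoA", "Glc", "Gal", "Man", "Fuc", "Xyl", "Rha",
             "Ara", "Rib", "Kdn", "Kdo")
  vocab <- vocab[order(-nchar(vocab))]
  s <- gsub("[[:space:]]", "", composition)
  if (!nzchar(s)) stop("empty composition string")
  counts <- integer(0)
  while (nzchar(s)) {
    hit <- NA_character_
    for (tok in vocab) {
      if (startsWith(s, tok)) { hit <- tok; break }
    }
    if (is.na(hit))
      stop("unparseable monosaccharide token at: '", s, "'")
    s <- substr(s, nchar(hit) + 1L, nchar(s))
    m <- regmatches(s, regexpr("^[0-9]+", s))
    k <- if (length(m)) as.integer(m) else 1L
    if (length(m)) s <- substr(s, nchar(m) + 1L, nchar(s))
    counts[hit] <- if (hit %in% names(counts)) counts[[hit]] + k else k
  }
  list(counts = counts, total = sum(counts))
}
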