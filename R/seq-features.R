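#' The 20 standard amino acids, one-letter codes
#'
#' Alphabetical order; this order fixes the layout of the monopeptide
#' (20), dipeptide (400, row-major over the same order) and scale-based
#' blocks of the descriptor vector.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Uppercase and drop non-standard letters (B, J, O, U, X, Z and anything
# else outside the 20-letter alphabet); the 20/400 composition blocks
# mandate the standard basis. Reports the number of removed characters.
clean_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  keep <- chars %in% amino_acids()
  removed <- sum(!keep)
  if (removed > 0) {
    inform(sprintf("Removed %d non-standard residue(s) from sequence", removed))
  }
  chars[keep]
}

#' Monopeptide (amino acid composition) frequencies
#'
#' @param seq Amino acid sequence (single string). Non-standard residues
#'   are removed before counting.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
monopeptide_frequencies <- function(seq) {
  chars <- clean_sequence(seq)
  if (length(chars) == 0) abort("Sequence is empty after removing non-standard residues")
  tab <- table(factor(chars, levels = amino_acids()))
  setNames(as.numeric(tab) / length(chars), amino_acids())
}

#' Dipeptide frequencies
#'
#' Frequency of each ordered residue pair among the L-1 overlapping
#' adjacent pairs, laid out row-major over the alphabetical one-letter
#' order (AA, AC, AD, ..., YW, YY).
#'
#' @param seq Amino acid sequence of cleaned length >= 2.
#' @return Named numeric vector of length 400 summing to 1.
#' @export
dipeptide_frequencies <- function(seq) {
  chars <- clean_sequence(seq)
  if (length(chars) < 2) abort("Dipeptide frequencies require a cleaned sequence of length >= 2")
  aas <- amino_acids()
  pair_names <- as.vector(t(outer(aas, aas, paste0)))
  pairs <- paste0(chars[-length(chars)], chars[-1])
  tab <- table(factor(pairs, levels = pair_names))
  setNames(as.numeric(tab) / (length(chars) - 1), pair_names)
}

# ---- amino acid index scales ------------------------------------------------

# The ten AAindex scales behind the physicochemical block. Values are
# read from the AAindex database shipped with seqinr, keyed by accession.
physchem_scales <- function() {
  tibble(
    accession = c(
      "KYTJ820101", "VINM940101", "CHAM820101", "CHAM820102", "CHAM810101",
      "GRAR740102", "ZIMJ680104", "BIGC670101", "FASG760101", "HOPT810101"
    ),
    family = c(
      "hydrophobicity", "flexibility", "polarizability", "free_energy",
      "steric", "polarity", "residue_pI", "volume", "residue_mass",
      "hydrophilicity"
    )
  )
}

get_aa_scales <- function() {
  if (!is.null(.dtirex_env$aa_scales)) return(.dtirex_env$aa_scales)
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  aaindex <- e$aaindex
  acc_of <- vapply(aaindex, `[[`, "", "H")
  scales <- physchem_scales()
  out <- lapply(scales$accession, function(a) {
    entry <- aaindex[[which(acc_of == a)]]
    v <- entry$I
    names(v) <- toupper(vapply(names(v), seqinr::a, "")) # 3-letter -> 1-letter
    v[amino_acids()]
  })
  names(out) <- scales$accession
  .dtirex_env$aa_scales <- out
  out
}

# EMBOSS pK values used for the isoelectric point.
iep_pk <- c(
  Nterm = 8.6, Cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1
)

protein_charge <- function(counts, pH) {
  pos <- c(Nterm = 1, K = counts[["K"]], R = counts[["R"]], H = counts[["H"]])
  neg <- c(Cterm = 1, D = counts[["D"]], E = counts[["E"]], C = counts[["C"]], Y = counts[["Y"]])
  q_pos <- sum(pos / (1 + 10^(pH - iep_pk[names(pos)])))
  q_neg <- sum(neg / (1 + 10^(iep_pk[names(neg)] - pH)))
  q_pos - q_neg
}

isoelectric_point <- function(chars) {
  counts <- table(factor(chars, levels = amino_acids()))
  counts <- setNames(as.numeric(counts), amino_acids())
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- protein_charge(counts, mid)
    if (abs(q) < 1e-9) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

# Unweighted sliding-window mean; window shrinks to the whole sequence
# when it is shorter than `w`.
window_means <- function(v, w = 9L) {
  n <- length(v)
  if (n <= w) return(mean(v))
  vapply(seq_len(n - w + 1L), function(i) mean(v[i:(i + w - 1L)]), numeric(1))
}

sd0 <- function(v) if (length(v) < 2) 0 else sd(v)

# Normalized Moreau-Broto autocorrelation at lag d of a per-residue
# profile standardized by the scale's own 20-value mean and sd.
autocorrelations <- function(z, lags) {
  n <- length(z)
  vapply(lags, function(d) {
    if (n <= d) return(0)
    mean(z[seq_len(n - d)] * z[seq_len(n - d) + d])
  }, numeric(1))
}

#' Physicochemical descriptor block (156 features)
#'
#' Six whole-sequence features -- length, molecular weight, aromaticity
#' (fraction of F/W/Y), instability index (Guruprasad dipeptide weights),
#' GRAVY (mean Kyte-Doolittle hydropathy) and isoelectric point (EMBOSS
#' pK set, bisection) -- followed by 15 statistics for each of ten amino
#' acid index scales (hydrophobicity, flexibility, polarizability, free
#' energy of solution, steric parameter, polarity, residue isoelectric
#' point, residue volume, residue mass, hydrophilicity): mean, sd, min,
#' max of the per-residue profile (for the flexibility scale these four
#' are computed on 9-residue sliding-window means) and normalized
#' Moreau-Broto autocorrelations at lags 1-11. The full manifest is
#' returned by [physchem_manifest()] and shipped as
#' `inst/extdata/physchem_manifest.tsv`.
#'
#' @param seq Amino acid sequence (single string).
#' @return Named numeric vector of length 156.
#' @export
physchem_features <- function(seq) {
  chars <- clean_sequence(seq)
  if (length(chars) == 0) abort("Sequence is empty after removing non-standard residues")
  L <- length(chars)
  scales <- get_aa_scales()

  # molecular weight from free amino acid masses (FASG760101), removing
  # one water (18.01524 Da) per peptide bond
  free_mw <- scales[["FASG760101"]]
  mol_weight <- sum(free_mw[chars]) - (L - 1) * 18.01524

  instability <- if (L < 2) 0 else {
    pairs_i <- match(chars[-L], rownames(diwv_table))
    pairs_j <- match(chars[-1], colnames(diwv_table))
    (10 / L) * sum(diwv_table[cbind(pairs_i, pairs_j)])
  }

  globals <- c(
    length = L,
    molecular_weight = mol_weight,
    aromaticity = mean(chars %in% c("F", "W", "Y")),
    instability_index = instability,
    gravy = mean(scales[["KYTJ820101"]][chars]),
    isoelectric_point = isoelectric_point(chars)
  )

  scale_feats <- unlist(lapply(physchem_scales()$accession, function(acc) {
    sc <- scales[[acc]]
    v <- unname(sc[chars])
    prof <- if (acc == "VINM940101") window_means(v, 9L) else v
    z <- (v - mean(sc)) / sd(sc)
    stats <- c(
      mean = mean(prof), sd = sd0(prof), min = min(prof), max = max(prof),
      setNames(autocorrelations(z, 1:11), paste0("mb", 1:11))
    )
    setNames(stats, paste0(tolower(acc), "_", names(stats)))
  }))

  c(globals, scale_feats)
}

#' Feature manifest for the physicochemical block
#'
#' @return Tibble with one row per feature: `index` (position within the
#'   156-feature block), `name`, `family`, `accession` (AAindex
#'   accession, `NA` for whole-sequence features) and `stat`.
#' @export
physchem_manifest <- function() {
  globals <- tibble(
    name = c("length", "molecular_weight", "aromaticity",
             "instability_index", "gravy", "isoelectric_point"),
    family = c("length", "mass", "aromaticity", "instability",
               "hydrophobicity", "isoelectric_point"),
    accession = c(NA, "FASG760101", NA, "DIWV_Guruprasad1990", "KYTJ820101", NA),
    stat = "global"
  )
  sc <- physchem_scales()
  stats <- c("mean", "sd", "min", "max", paste0("mb", 1:11))
  per_scale <- tidyr::crossing(
    dplyr::select(sc, "accession", "family"),
    tibble(stat = factor(stats, levels = stats))
  ) |>
    arrange(match(.data$accession, sc$accession), .data$stat) |>
    mutate(stat = as.character(.data$stat),
           name = paste0(tolower(.data$accession), "_", .data$stat)) |>
    select("name", "family", "accession", "stat")
  out <- bind_rows(globals, per_scale)
  mutate(out, index = row_number(), .before = 1)
}

#' Compute the full 576-dimensional sequence descriptor vector
#'
#' Concatenates 20 monopeptide frequencies, 400 dipeptide frequencies
#' and 156 physicochemical features, in that fixed order.
#'
#' @param seq Amino acid sequence (single string).
#' @return Named numeric vector of length 576.
#' @export
#' @examples
#' length(compute_descriptors("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"))
compute_descriptors <- function(seq) {
  c(monopeptide_frequencies(seq), dipeptide_frequencies(seq), physchem_features(seq))
}

#' L2-normalize a vector or the rows of a matrix
#'
#' Divides by the Euclidean norm; an all-zero vector (or row) is
#' returned unchanged with a warning.
#'
#' @param x Numeric vector, or matrix whose rows are normalized
#'   independently.
#' @return Object of the same shape with unit Euclidean norm (where the
#'   input was nonzero).
#' @export
#' @examples
#' l2_normalize(c(3, 4))
l2_normalize <- function(x) {
  if (is.matrix(x)) {
    norms <- sqrt(rowSums(x^2))
    zero <- norms == 0
    if (any(zero)) warn(sprintf("%d all-zero row(s) left unnormalized", sum(zero)))
    norms[zero] <- 1
    return(x / norms)
  }
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) {
    warn("All-zero vector left unnormalized")
    return(x)
  }
  x / nrm
}

#' Compute descriptors for a set of sequences
#'
#' @param sequences Named character vector of amino acid sequences (or a
#'   FASTA path via [featurize_fasta()]).
#' @param l2 Normalize each descriptor vector to unit Euclidean norm.
#' @return Tibble with an `id` column and 576 feature columns.
#' @export
featurize <- function(sequences, l2 = FALSE) {
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  mat <- do.call(rbind, lapply(sequences, compute_descriptors))
  if (l2) mat <- l2_normalize(mat)
  out <- as_tibble(mat)
  out <- mutate(out, id = ids, .before = 1)
  out
}

#' Compute descriptors for every record of a FASTA file
#'
#' @param path FASTA file (standard multi-record, read with seqinr).
#' @param l2 Normalize each descriptor vector to unit Euclidean norm.
#' @return Tibble with an `id` column and 576 feature columns.
#' @export
featurize_fasta <- function(path, l2 = FALSE) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  seqs <- setNames(vapply(recs, function(r) as.character(r)[1], ""), names(recs))
  featurize(seqs, l2 = l2)
}

#' Extract the numeric feature matrix from a featurize() tibble
#'
#' @param features Tibble from [featurize()] / [featurize_fasta()].
#' @return Numeric matrix with rownames from the `id` column.
#' @export
feature_matrix <- function(features) {
  mat <- as.matrix(select(features, -"id"))
  rownames(mat) <- features$id
  mat
}
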