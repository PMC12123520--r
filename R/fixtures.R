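# Bundled 12-subject hand-swab washing study, shipped at the count level:
# per-sample expected/detected/drop-in allele counts for the pre-wash
# (HSWW, hand swab without wash) and post-wash (HSWA, hand swab after
# antibacterial soap + alcohol sanitizer) conditions, and per-locus
# detection scores for the post-wash profiles. Full genotypes were not
# published, so the comparison engine is exercised on simulated profiles
# while the statistics pipeline runs on these records.

#' Load the bundled hand-swab washing study
#'
#' The dataset covers twelve subjects (six male, six female), each typed
#' from a buccal reference swab and sampled from the palms twice: once
#' before washing (condition \code{HSWW}) and once immediately after
#' washing with antibacterial soap followed by alcohol-based sanitizer
#' (condition \code{HSWA}). It is shipped as two delimited tables:
#' per-sample allele counts, and a per-locus detection score matrix for the
#' post-wash profiles (1 = all reference alleles at the locus detected,
#' 0.5 = one of two heterozygous alleles, 0 = none; Y-STR cells are absent
#' for female subjects).
#'
#' @return A list with components:
#'   \describe{
#'     \item{records}{Data frame of 24 comparison records (12 samples x 2
#'       conditions) with columns \code{sample_id}, \code{sex},
#'       \code{condition}, \code{expected}, \code{detected},
#'       \code{drop_in}, \code{drop_out}, \code{recovery_pct}.}
#'     \item{scores}{Numeric matrix, 26 STR loci x 12 samples, of post-wash
#'       locus detection scores in \{0, 0.5, 1\}; \code{NA} for female
#'       Y-STR cells.}
#'     \item{reference_counts}{Named integer vector of expected (reference)
#'       autosomal allele counts per sample.}
#'   }
#' @examples
#' study <- load_study_data()
#' subset(study$records, condition == "HSWA")$detected
#' @export
load_study_data <- function() {
  counts_path <- system.file("extdata", "hand_swab_counts.csv",
                             package = "strwash", mustWork = TRUE)
  scores_path <- system.file("extdata", "hand_swab_locus_scores.csv",
                             package = "strwash", mustWork = TRUE)
  counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  records <- rbind(
    make_records(counts, "HSWW", counts$hsww_detected, counts$hsww_dropin),
    make_records(counts, "HSWA", counts$hswa_detected, counts$hswa_dropin)
  )
  rownames(records) <- NULL

  raw <- utils::read.csv(scores_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  scores <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(scores) <- "numeric")  # "-" cells -> NA
  rownames(scores) <- raw$locus
  validate_score_matrix(scores)

  ref <- counts$reference_alleles
  names(ref) <- counts$sample_id
  list(records = records, scores = scores, reference_counts = ref)
}

make_records <- function(counts, condition, detected, drop_in) {
  comparison_records(
    sample_id = counts$sample_id,
    sex = unname(vapply(counts$sample_id, infer_sex, "")),
    condition = condition,
    expected = counts$reference_alleles,
    detected = detected,
    drop_in = drop_in
  )
}

#' Build a table of comparison records from counts
#'
#' A comparison record holds, for one evidence/reference pair, the expected
#' allele count E (autosomal alleles in the reference profile), the detected
#' count D (reference alleles recovered in the evidence), drop-in count I
#' (evidence alleles foreign to the reference), the derived drop-out count
#' O = E - D and the recovery percentage R = 100 D / E.
#'
#' @param sample_id,sex,condition,expected,detected,drop_in Vectors, recycled
#'   to a common length.
#' @return Data frame with the derived \code{drop_out} and
#'   \code{recovery_pct} columns appended. Counts are validated:
#'   \code{0 <= D <= E <= 46} and \code{I >= 0}; \code{E = 0} is an error
#'   because the recovery percentage is undefined.
#' @export
comparison_records <- function(sample_id, sex = "unknown", condition = NA,
                               expected, detected, drop_in = 0L) {
  rec <- data.frame(sample_id = as.character(sample_id),
                    sex = sex, condition = condition,
                    expected = as.integer(expected),
                    detected = as.integer(detected),
                    drop_in = as.integer(drop_in),
                    stringsAsFactors = FALSE)
  if (any(rec$expected <= 0))
    stop("expected allele count must be positive (recovery undefined at E = 0)")
  if (any(rec$expected > 46))
    stop("expected count exceeds the autosomal maximum of 46 (= 2 x 23)")
  if (any(rec$detected < 0 | rec$detected > rec$expected))
    stop("detected count must lie in [0, expected]")
  if (any(rec$drop_in < 0)) stop("drop-in count must be non-negative")
  rec$drop_out <- rec$expected - rec$detected
  rec$recovery_pct <- 100 * rec$detected / rec$expected
  rec
}

validate_score_matrix <- function(scores) {
  vals <- scores[!is.na(scores)]
  if (!all(vals %in% c(0, 0.5, 1)))
    stop("locus detection scores must be 0, 0.5 or 1")
  panel <- fusion6c_panel()
  if (!setequal(rownames(scores), panel_loci(panel, c("autosomal", "y_str"))))
    stop("score matrix rows must be the 26 STR loci of the panel")
  ylocs <- panel_loci(panel, "y_str")
  na_cells <- which(is.na(scores), arr.ind = TRUE)
  if (nrow(na_cells)) {
    ok <- rownames(scores)[na_cells[, 1]] %in% ylocs &
      startsWith(colnames(scores)[na_cells[, 2]], "F")
    if (!all(ok))
      stop("missing scores allowed only at Y-STR loci of female samples")
  }
  invisible(scores)
}

#' Allele-count bounds implied by a locus score column
#'
#' A locus scored 0.5 contributes exactly one detected allele; a locus
#' scored 1 contributes one (homozygote) or two (heterozygote). The total
#' detected autosomal count D for a sample is therefore bracketed by
#' \code{n05 + n1 <= D <= n05 + 2 n1}, where \code{n05}, \code{n1} count
#' autosomal loci scored 0.5 and 1. Used as a cross-table consistency check
#' between the count records and the score matrix.
#'
#' @param scores Score matrix as in \code{\link{load_study_data}}.
#' @param panel Locus panel.
#' @return Data frame with columns \code{sample_id}, \code{n05}, \code{n1},
#'   \code{lower}, \code{upper}.
#' @export
score_count_bounds <- function(scores, panel = fusion6c_panel()) {
  aut <- intersect(rownames(scores), panel_loci(panel, "autosomal"))
  sub <- scores[aut, , drop = FALSE]
  n05 <- colSums(sub == 0.5, na.rm = TRUE)
  n1 <- colSums(sub == 1, na.rm = TRUE)
  data.frame(sample_id = colnames(scores), n05 = as.integer(n05),
             n1 = as.integer(n1), lower = as.integer(n05 + n1),
             upper = as.integer(n05 + 2L * n1), stringsAsFactors = FALSE)
}
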