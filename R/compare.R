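# Evidence-vs-reference comparison. All counting is over the 23 autosomal
# loci: amelogenin and Y-STR calls are reported in a per-locus detail table
# but never enter expected/detected/drop-in/drop-out tallies.

#' Expected allele count of a reference profile
#'
#' Counts distinct allele designations over the autosomal loci of a
#' single-source reference profile: a heterozygous locus contributes 2, a
#' homozygous locus 1. Amelogenin and Y-STR calls are excluded.
#'
#' @param reference An \code{str_profile} with at least one autosomal call.
#' @param panel Locus panel.
#' @return Integer count in [1, 46].
#' @export
expected_allele_count <- function(reference, panel = fusion6c_panel()) {
  stopifnot(inherits(reference, "str_profile"))
  aut <- panel_loci(panel, "autosomal")
  calls <- reference$calls[reference$calls$locus %in% aut, , drop = FALSE]
  if (!nrow(calls))
    stop("reference profile '", reference$sample_id,
         "' has no autosomal calls")
  n <- sum(!duplicated(paste(calls$locus, calls$allele, sep = "\r")))
  as.integer(n)
}

#' Compare an evidence profile against its reference
#'
#' Per autosomal locus, a reference allele present in the evidence (same
#' locus, same designation) is detected; a reference allele absent from the
#' evidence has dropped out; an evidence allele absent from the reference is
#' a drop-in. Evidence alleles at autosomal loci where the reference has no
#' calls also count as drop-in. The recovery percentage is
#' \code{100 * detected / expected}.
#'
#' @param evidence,reference \code{str_profile}s on the same panel.
#' @param panel Locus panel.
#' @param condition Optional condition label stored in the record
#'   (e.g. \code{"HSWW"}, \code{"HSWA"}).
#' @return One-row comparison-record data frame (see
#'   \code{\link{comparison_records}}) with attribute \code{"detail"}: a
#'   per-locus data frame covering all panel loci (including Y-STR and
#'   amelogenin, flagged by \code{counted = FALSE}) with per-locus expected,
#'   detected and drop-in tallies.
#' @export
compare_profiles <- function(evidence, reference, panel = fusion6c_panel(),
                             condition = NA) {
  stopifnot(inherits(evidence, "str_profile"),
            inherits(reference, "str_profile"))
  detail <- do.call(rbind, lapply(panel$locus, function(loc) {
    ref <- profile_alleles(reference, loc)
    ev <- profile_alleles(evidence, loc)
    data.frame(locus = loc,
               kind = panel$kind[panel$locus == loc],
               expected = length(ref),
               detected = length(intersect(ref, ev)),
               drop_in = length(setdiff(ev, ref)),
               stringsAsFactors = FALSE)
  }))
  detail$drop_out <- detail$expected - detail$detected
  detail$counted <- detail$kind == "autosomal"
  aut <- detail[detail$counted, , drop = FALSE]
  if (sum(aut$expected) == 0)
    stop("reference profile '", reference$sample_id,
         "' has no autosomal calls")
  rec <- comparison_records(sample_id = evidence$sample_id,
                            sex = reference$sex, condition = condition,
                            expected = sum(aut$expected),
                            detected = sum(aut$detected),
                            drop_in = sum(aut$drop_in))
  attr(rec, "detail") <- detail
  rec
}

#' Locus detection score
#'
#' Scores how completely the reference genotype at one STR locus is
#' recovered in the evidence: 1 when every reference allele is detected
#' (both alleles of a heterozygote, or the single allele of a homozygote),
#' 0.5 when exactly one of two heterozygous alleles is detected, 0 when
#' none is.
#'
#' @param evidence,reference \code{str_profile}s.
#' @param locus An STR locus name at which the reference has a genotype.
#' @param panel Locus panel.
#' @return 0, 0.5 or 1.
#' @export
locus_score <- function(evidence, reference, locus,
                        panel = fusion6c_panel()) {
  kind <- panel$kind[panel$locus == locus]
  if (!length(kind) || kind == "amelogenin")
    stop("'", locus, "' is not an STR locus of the panel")
  ref <- profile_alleles(reference, locus)
  if (!length(ref))
    stop("reference '", reference$sample_id,
         "' has no genotype at locus ", locus)
  hit <- length(intersect(ref, profile_alleles(evidence, locus)))
  if (hit == length(ref)) 1
  else if (hit == 1L && length(ref) == 2L) 0.5
  else 0
}

#' Locus detection score matrix for evidence/reference pairs
#'
#' @param pairs Non-empty list of \code{list(evidence = , reference = )}
#'   pairs.
#' @param panel Locus panel.
#' @return Numeric matrix, STR loci (rows, panel order) x samples (columns,
#'   evidence sample IDs). Cells are \code{NA} where the reference has no
#'   genotype (Y-STR loci of female subjects).
#' @export
score_matrix <- function(pairs, panel = fusion6c_panel()) {
  if (!length(pairs)) stop("'pairs' must be non-empty")
  loci <- panel_loci(panel, c("autosomal", "y_str"))
  cols <- lapply(pairs, function(p) {
    vapply(loci, function(loc) {
      if (!length(profile_alleles(p$reference, loc))) NA_real_
      else locus_score(p$evidence, p$reference, loc, panel)
    }, numeric(1))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(pairs, function(p) p$evidence$sample_id, "")
  rownames(m) <- loci
  m
}
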