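# Seeded simulator of the two-condition hand-swab design: reference
# genotypes over the Fusion 6C panel, condition-dependent per-allele
# detection (washing modelled as a collapse of the detection probability),
# shedder-status variability, sporadic drop-in, and peak-height mixtures.
#
# Randomness flows through R's global RNG: seed once (set.seed, or the
# `seed` argument of simulate_study) and an identical seed reproduces the
# whole study.

#' Allele frequency model
#'
#' Per-locus allele frequencies used to draw reference genotypes and
#' drop-in alleles. The default is uniform over \code{n_alleles} synthetic
#' repeat designations per STR locus — no published population table is
#' required — but any mapping can be supplied as long as frequencies are
#' positive and sum to one per locus.
#'
#' @param panel Locus panel.
#' @param n_alleles Number of equifrequent alleles per locus for the
#'   default model.
#' @param freqs Optional named list: locus -> named numeric vector of
#'   frequencies (names are allele designations). Must cover every STR
#'   locus of the panel.
#' @return Named list of class \code{allele_freq_model}.
#' @export
allele_freq_model <- function(panel = fusion6c_panel(), n_alleles = 8L,
                              freqs = NULL) {
  loci <- panel_loci(panel, c("autosomal", "y_str"))
  if (is.null(freqs)) {
    designations <- as.character(seq(8L, length.out = n_alleles))
    freqs <- stats::setNames(
      rep(list(stats::setNames(rep(1 / n_alleles, n_alleles), designations)),
          length(loci)),
      loci)
  }
  missing <- setdiff(loci, names(freqs))
  if (length(missing))
    stop("frequency model missing loci: ", paste(missing, collapse = ", "))
  for (loc in loci) {
    f <- freqs[[loc]]
    if (any(f <= 0) || abs(sum(f) - 1) > 1e-9)
      stop("frequencies at ", loc, " must be positive and sum to 1")
  }
  structure(freqs[loci], class = "allele_freq_model")
}

#' Simulation parameters
#'
#' @param p_detect Per-allele detection probability for an intermediate
#'   shedder, in [0, 1]. The effective probability is
#'   \code{min(1, p_detect * shedder multiplier)}.
#' @param dropin_rate Expected number of sporadic foreign (drop-in) alleles
#'   per evidence profile (Poisson mean), at autosomal loci.
#' @param shedder_multipliers Positive factors scaling \code{p_detect} per
#'   shedder class (\code{high}, \code{intermediate}, \code{low}).
#' @param height_mean Mean simulated peak height in RFU.
#' @param height_cv Coefficient of variation of the lognormal peak-height
#'   noise (0 switches noise off).
#' @return List of class \code{sim_params}.
#' @export
sim_params <- function(p_detect, dropin_rate = 0,
                       shedder_multipliers = c(high = 1.15,
                                               intermediate = 1,
                                               low = 0.6),
                       height_mean = 1000, height_cv = 0.2) {
  stopifnot(p_detect >= 0, p_detect <= 1, dropin_rate >= 0,
            all(shedder_multipliers > 0), height_mean > 0, height_cv >= 0)
  if (!all(c("high", "intermediate", "low") %in% names(shedder_multipliers)))
    stop("shedder_multipliers needs names high, intermediate, low")
  structure(list(p_detect = p_detect, dropin_rate = dropin_rate,
                 shedder_multipliers = shedder_multipliers,
                 height_mean = height_mean, height_cv = height_cv),
            class = "sim_params")
}

#' Default pre-wash scenario parameters
#'
#' Detection probability 0.8 (the typical pre-wash subject recovers about
#' 80\% of reference alleles) with around two sporadic drop-in alleles per
#' profile.
#' @return A \code{\link{sim_params}} object.
#' @export
sim_params_prewash <- function() sim_params(p_detect = 0.8, dropin_rate = 2)

#' Default post-wash scenario parameters
#'
#' Near-total allele loss after soap-plus-sanitizer washing: detection
#' probability 0.04 and no drop-in. This is a scenario parameter chosen to
#' emulate the washed condition, not an estimate from any dataset.
#' @return A \code{\link{sim_params}} object.
#' @export
sim_params_postwash <- function() sim_params(p_detect = 0.04, dropin_rate = 0)

draw_allele <- function(freqs, exclude = character()) {
  pool <- freqs[!(names(freqs) %in% exclude)]
  if (!length(pool)) stop("no alleles left to draw from")
  sample(names(pool), 1L, prob = pool)
}

#' Draw a single-source reference genotype
#'
#' Two independent allele draws per autosomal locus (identical draws
#' collapse to a homozygote), one draw per Y-STR locus for males, none for
#' females, and amelogenin X,X or X,Y by sex.
#'
#' @param sample_id Sample identifier.
#' @param sex \code{"male"} or \code{"female"}.
#' @param freq_model An \code{\link{allele_freq_model}}.
#' @param panel Locus panel.
#' @return An \code{str_profile} (no heights).
#' @export
sample_reference_profile <- function(sample_id, sex = c("male", "female"),
                                     freq_model = allele_freq_model(),
                                     panel = fusion6c_panel()) {
  sex <- match.arg(sex)
  rows <- list()
  for (loc in panel_loci(panel, "autosomal")) {
    f <- freq_model[[loc]]
    a <- sample(names(f), 2L, replace = TRUE, prob = f)
    rows[[loc]] <- data.frame(locus = loc, allele = unique(a),
                              stringsAsFactors = FALSE)
  }
  if (sex == "male") {
    for (loc in panel_loci(panel, "y_str")) {
      rows[[loc]] <- data.frame(locus = loc,
                                allele = draw_allele(freq_model[[loc]]),
                                stringsAsFactors = FALSE)
    }
  }
  amel <- if (sex == "male") c("X", "Y") else "X"
  rows[["amel"]] <- data.frame(locus = .AMELOGENIN, allele = amel,
                               stringsAsFactors = FALSE)
  str_profile(sample_id, do.call(rbind, rows), sex = sex, panel = panel)
}

lognormal_heights <- function(n, mean_rfu, cv) {
  if (cv == 0) return(rep(mean_rfu, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean_rfu) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an evidence profile from a reference
#'
#' Each reference allele (autosomal, Y-STR and amelogenin alike) is
#' retained independently with probability
#' \code{min(1, p_detect * multiplier(shedder))}; allele detections within
#' a heterozygote are independent. \code{Poisson(dropin_rate)} sporadic
#' foreign alleles are added at uniformly drawn autosomal loci, each drawn
#' from the frequency model and redrawn while it collides with a reference
#' allele at that locus. Every retained call receives a lognormal peak
#' height.
#'
#' @param reference An \code{str_profile}.
#' @param params A \code{\link{sim_params}} object.
#' @param shedder Shedder class of the subject (\code{"high"},
#'   \code{"intermediate"}, \code{"low"}).
#' @param freq_model Frequency model for drop-in draws.
#' @param panel Locus panel.
#' @return An \code{str_profile} with heights.
#' @export
simulate_evidence <- function(reference, params,
                              shedder = "intermediate",
                              freq_model = allele_freq_model(),
                              panel = fusion6c_panel()) {
  stopifnot(inherits(reference, "str_profile"), inherits(params, "sim_params"))
  p <- min(1, params$p_detect * params$shedder_multipliers[[shedder]])
  calls <- reference$calls
  keep <- calls[stats::runif(nrow(calls)) < p, c("locus", "allele"),
                drop = FALSE]
  n_dropin <- stats::rpois(1L, params$dropin_rate)
  if (n_dropin > 0) {
    aut <- panel_loci(panel, "autosomal")
    din <- do.call(rbind, lapply(seq_len(n_dropin), function(i) {
      loc <- sample(aut, 1L)
      data.frame(locus = loc,
                 allele = draw_allele(freq_model[[loc]],
                                      exclude = profile_alleles(reference, loc)),
                 stringsAsFactors = FALSE)
    }))
    keep <- rbind(keep, din)
  }
  keep$height <- lognormal_heights(nrow(keep), params$height_mean,
                                   params$height_cv)
  str_profile(reference$sample_id, keep, sex = reference$sex, panel = panel)
}

#' Simulate a full two-condition washing study
#'
#' Emulates the study design end to end: \code{n_subjects} subjects (half
#' male, half female by default), one reference genotype each, a pre-wash
#' evidence profile drawn under \code{params_pre} and a post-wash profile
#' under \code{params_post}, each compared against the reference with
#' \code{\link{compare_profiles}}.
#'
#' @param n_subjects Even count >= 2.
#' @param params_pre,params_post \code{\link{sim_params}} for the two
#'   conditions; default to the study-scenario parameters.
#' @param shedder_assignment Optional character vector (length
#'   \code{n_subjects}) of shedder classes; by default each subject is
#'   assigned uniformly at random among high/intermediate/low.
#' @param seed Integer seed; set before any draws so an identical seed
#'   reproduces the study.
#' @param freq_model Frequency model.
#' @param panel Locus panel.
#' @return Comparison-record data frame with 2 \code{n_subjects} rows,
#'   conditions labelled \code{HSWW} (pre-wash) and \code{HSWA}
#'   (post-wash). The simulated profiles are attached as attribute
#'   \code{"profiles"} (list with \code{reference}, \code{pre}, \code{post}
#'   per subject).
#' @export
simulate_study <- function(n_subjects = 12L,
                           params_pre = sim_params_prewash(),
                           params_post = sim_params_postwash(),
                           shedder_assignment = NULL,
                           seed = NULL,
                           freq_model = allele_freq_model(),
                           panel = fusion6c_panel()) {
  stopifnot(n_subjects >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_male <- ceiling(n_subjects / 2)
  ids <- c(paste0("M", seq_len(n_male)),
           paste0("F", seq_len(n_subjects - n_male)))
  sexes <- c(rep("male", n_male), rep("female", n_subjects - n_male))
  if (is.null(shedder_assignment))
    shedder_assignment <- sample(c("high", "intermediate", "low"),
                                 n_subjects, replace = TRUE)
  stopifnot(length(shedder_assignment) == n_subjects)
  profiles <- vector("list", n_subjects)
  recs <- vector("list", 2L * n_subjects)
  for (i in seq_len(n_subjects)) {
    ref <- sample_reference_profile(ids[i], sexes[i], freq_model, panel)
    pre <- simulate_evidence(ref, params_pre, shedder_assignment[i],
                             freq_model, panel)
    post <- simulate_evidence(ref, params_post, shedder_assignment[i],
                              freq_model, panel)
    profiles[[i]] <- list(reference = ref, pre = pre, post = post,
                          shedder = shedder_assignment[i])
    recs[[2 * i - 1]] <- compare_profiles(pre, ref, panel, condition = "HSWW")
    recs[[2 * i]] <- compare_profiles(post, ref, panel, condition = "HSWA")
  }
  out <- do.call(rbind, lapply(recs, function(r) { attr(r, "detail") <- NULL; r }))
  rownames(out) <- NULL
  names(profiles) <- ids
  attr(out, "profiles") <- profiles
  out
}

#' Pooled detection-probability estimate
#'
#' Diagnostic estimator \code{sum(detected) / sum(expected)} over a set of
#' comparison records; recovers \code{p_detect} of the generating scenario
#' when drop-in is off and all subjects share a shedder class.
#'
#' @param records Comparison-record data frame.
#' @return Estimate in [0, 1].
#' @export
estimate_detection_probability <- function(records) {
  if (!nrow(records)) stop("no records")
  tot <- sum(records$expected)
  if (tot == 0) stop("zero total expected alleles")
  sum(records$detected) / tot
}

#' Build a two-or-more-person mixture profile
#'
#' Takes the union of the contributors' alleles per locus; the expected
#' peak height of an allele is proportional to the summed mixing ratios of
#' the contributors carrying it (\code{height_mean} RFU per unit ratio),
#' with lognormal noise governed by \code{height_cv}.
#'
#' @param profiles List of >= 2 \code{str_profile} contributors.
#' @param ratios Positive mixing ratios, one per contributor.
#' @param params \code{\link{sim_params}} (only the height model is used).
#' @param sample_id Identifier for the mixed profile.
#' @param panel Locus panel.
#' @return An \code{str_profile} with heights.
#' @export
make_mixture <- function(profiles, ratios, params = sim_params(1),
                         sample_id = "mixture", panel = fusion6c_panel()) {
  if (length(profiles) < 2) stop("need at least two contributors")
  if (length(ratios) != length(profiles) || any(ratios <= 0))
    stop("'ratios' must be positive, one per contributor")
  alle <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    calls <- profiles[[i]]$calls
    data.frame(locus = calls$locus, allele = calls$allele,
               ratio = ratios[i], stringsAsFactors = FALSE)
  }))
  key <- paste(alle$locus, alle$allele, sep = "\r")
  wt <- tapply(alle$ratio, key, sum)
  first <- !duplicated(key)
  mix <- alle[first, c("locus", "allele"), drop = FALSE]
  expected <- params$height_mean *
    as.numeric(wt[paste(mix$locus, mix$allele, sep = "\r")])
  noise <- if (params$height_cv == 0) rep(1, nrow(mix))
  else lognormal_heights(nrow(mix), 1, params$height_cv)
  mix$height <- expected * noise
  sexes <- unique(vapply(profiles, function(p) p$sex, ""))
  sex <- if (length(sexes) == 1L) sexes else "unknown"
  str_profile(sample_id, mix, sex = sex, panel = panel)
}
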