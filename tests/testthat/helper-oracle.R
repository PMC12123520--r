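# Test helpers: quick profile builders, a brute-force comparison oracle
# that enumerates (locus, allele) pairs with plain loops, and a random
# small-profile generator for property tests.

profiles_equal <- strwash:::profiles_equal
trunc2 <- strwash:::trunc2

# profile from a named list: locus -> character vector of alleles
# (or a named numeric vector allele -> height)
quick_profile <- function(sample_id, loci, sex = "unknown") {
  rows <- list()
  for (loc in names(loci)) {
    x <- loci[[loc]]
    if (is.null(names(x))) {
      rows[[loc]] <- data.frame(locus = loc, allele = as.character(x),
                                height = NA_real_, stringsAsFactors = FALSE)
    } else {
      rows[[loc]] <- data.frame(locus = loc, allele = names(x),
                                height = as.numeric(x),
                                stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else NULL
  str_profile(sample_id, calls, sex = sex)
}

# independent comparison oracle: walk every (locus, allele) pair directly
oracle_compare <- function(evidence, reference, panel = fusion6c_panel()) {
  aut <- panel$locus[panel$kind == "autosomal"]
  expected <- 0L; detected <- 0L; drop_in <- 0L
  for (loc in aut) {
    ref <- unique(reference$calls$allele[reference$calls$locus == loc])
    ev <- unique(evidence$calls$allele[evidence$calls$locus == loc])
    for (a in ref) {
      expected <- expected + 1L
      found <- FALSE
      for (b in ev) if (identical(a, b)) found <- TRUE
      if (found) detected <- detected + 1L
    }
    for (b in ev) {
      foreign <- TRUE
      for (a in ref) if (identical(a, b)) foreign <- FALSE
      if (foreign) drop_in <- drop_in + 1L
    }
  }
  list(expected = expected, detected = detected, drop_in = drop_in,
       drop_out = expected - detected)
}

# random pair of small profiles: reference genotypes at <= max_loci
# autosomal loci, evidence a noisy subset plus foreign alleles
random_small_pair <- function(max_loci = 5L) {
  panel <- fusion6c_panel()
  aut <- panel$locus[panel$kind == "autosomal"]
  loci <- sample(aut, sample.int(max_loci, 1L))
  pool <- as.character(8:13)
  ref_rows <- list(); ev_rows <- list()
  for (loc in loci) {
    ref <- sample(pool, sample(1:2, 1L))
    keep <- ref[runif(length(ref)) < 0.7]
    foreign <- setdiff(pool, ref)
    extra <- sample(foreign, rpois(1L, 0.5))
    ev <- c(keep, extra)
    ref_rows[[loc]] <- data.frame(locus = loc, allele = ref,
                                  stringsAsFactors = FALSE)
    if (length(ev))
      ev_rows[[loc]] <- data.frame(locus = loc, allele = ev,
                                   stringsAsFactors = FALSE)
  }
  # evidence sometimes covers a locus the reference lacks
  if (runif(1) < 0.3) {
    loc <- sample(setdiff(aut, loci), 1L)
    ev_rows[[loc]] <- data.frame(locus = loc,
                                 allele = sample(pool, 1L),
                                 stringsAsFactors = FALSE)
  }
  list(
    reference = str_profile("R1", do.call(rbind, ref_rows)),
    evidence = str_profile("R1", if (length(ev_rows))
      do.call(rbind, ev_rows) else NULL)
  )
}
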