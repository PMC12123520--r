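# STR profiles: one sample's called alleles per locus, optionally with
# peak heights (RFU). Allele designations are text and are compared by
# exact string equality after trimming, so microvariants such as "13.3"
# stay distinct from "13" and amelogenin carries "X"/"Y".

#' Construct an STR profile
#'
#' @param sample_id Sample identifier (non-empty string).
#' @param calls Data frame with columns \code{locus}, \code{allele} and
#'   optionally \code{height} (RFU, non-negative or \code{NA}). One row per
#'   called allele; duplicate (locus, allele) rows are collapsed keeping the
#'   maximum height.
#' @param sex One of \code{"male"}, \code{"female"}, \code{"unknown"}.
#' @param panel Panel the profile lives on; defaults to
#'   \code{\link{fusion6c_panel}()}. Calls at loci outside the panel are an
#'   error, as are Y-STR calls in a female profile.
#' @return An object of class \code{str_profile}.
#' @export
str_profile <- function(sample_id, calls = NULL,
                        sex = c("unknown", "male", "female"),
                        panel = fusion6c_panel()) {
  sex <- match.arg(sex)
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("'sample_id' must be a non-empty string")
  if (is.null(calls))
    calls <- data.frame(locus = character(), allele = character(),
                        height = numeric(), stringsAsFactors = FALSE)
  if (!all(c("locus", "allele") %in% names(calls)))
    stop("'calls' needs columns 'locus' and 'allele'")
  if (is.null(calls$height)) calls$height <- NA_real_
  calls <- data.frame(locus = as.character(calls$locus),
                      allele = canonical_allele(calls$allele),
                      height = as.numeric(calls$height),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(calls$allele)))
    stop("empty allele designation")
  if (any(!is.na(calls$height) & calls$height < 0))
    stop("negative peak height")
  bad <- setdiff(unique(calls$locus), panel$locus)
  if (length(bad))
    stop("unknown locus name(s): ", paste(bad, collapse = ", "))
  if (sex == "female") {
    y <- panel_loci(panel, "y_str")
    if (any(calls$locus %in% y))
      stop("female profile '", sample_id, "' has Y-STR calls")
  }
  # collapse duplicate (locus, allele), keep tallest peak
  if (nrow(calls)) {
    key <- paste(calls$locus, calls$allele, sep = "\r")
    if (anyDuplicated(key)) {
      h <- tapply(calls$height, key, function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      first <- !duplicated(key)
      calls <- calls[first, , drop = FALSE]
      calls$height <- as.numeric(h[paste(calls$locus, calls$allele, sep = "\r")])
    }
    calls <- calls[order(match(calls$locus, panel$locus), calls$allele), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  structure(list(sample_id = sample_id, sex = sex, calls = calls),
            class = "str_profile")
}

# trim whitespace; strip a trailing ".0" style zero is NOT done -- "13.0"
# and "13" are distinct designations, but leading/trailing blanks and
# numeric formatting like "13" vs " 13 " collapse.
canonical_allele <- function(x) trimws(as.character(x))

#' Alleles called at one locus of a profile
#'
#' @param profile An \code{str_profile}.
#' @param locus Locus name.
#' @return Character vector of distinct allele designations (possibly empty).
#' @export
profile_alleles <- function(profile, locus) {
  stopifnot(inherits(profile, "str_profile"))
  unique(profile$calls$allele[profile$calls$locus == locus])
}

#' @export
print.str_profile <- function(x, ...) {
  cat(sprintf("STR profile %s (%s): %d calls at %d loci\n", x$sample_id,
              x$sex, nrow(x$calls), length(unique(x$calls$locus))))
  invisible(x)
}

#' @export
format.str_profile <- function(x, ...) {
  sprintf("<str_profile %s>", x$sample_id)
}

# equality up to call order; heights compared with NA == NA
profiles_equal <- function(a, b) {
  if (a$sample_id != b$sample_id || a$sex != b$sex) return(FALSE)
  ka <- a$calls[order(a$calls$locus, a$calls$allele), ]
  kb <- b$calls[order(b$calls$locus, b$calls$allele), ]
  if (nrow(ka) != nrow(kb)) return(FALSE)
  all(ka$locus == kb$locus) && all(ka$allele == kb$allele) &&
    isTRUE(all.equal(ka$height, kb$height))
}

#' Read STR profiles from a genotype table
#'
#' The genotype-table dialect is a UTF-8 comma-separated file with header
#' \code{sample_id,locus,allele,height}; \code{height} is blank when no peak
#' height is available. One row per called allele. Sample sex, when not given
#' via \code{sex}, is inferred from the sample ID prefix: IDs starting with
#' \code{M} are male, \code{F} female, anything else unknown.
#'
#' @param path Path to the file.
#' @param panel Locus panel used to validate locus names.
#' @param sex Optional named character vector mapping sample ID to sex,
#'   overriding the prefix rule.
#' @return List of \code{str_profile}, one per distinct sample ID, in order
#'   of first appearance.
#' @export
read_profiles <- function(path, panel = fusion6c_panel(), sex = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file (missing header): ", path)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  want <- c("sample_id", "locus", "allele", "height")
  if (!identical(trimws(header), want))
    stop("bad header, expected 'sample_id,locus,allele,height' in ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(list())
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  # a trailing empty height field may be dropped by strsplit; normalise
  parts[nfield == 3L] <- lapply(parts[nfield == 3L], function(p) c(p, ""))
  bad <- which(!(nfield %in% c(3L, 4L)))
  if (length(bad))
    stop("malformed row (wrong column count) at line ", bad[[1]] + 1L,
         " of ", path)
  tab <- data.frame(
    sample_id = trimws(vapply(parts, `[[`, "", 1L)),
    locus = trimws(vapply(parts, `[[`, "", 2L)),
    allele = vapply(parts, `[[`, "", 3L),
    height_raw = trimws(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  unknown <- which(!(tab$locus %in% panel$locus))
  if (length(unknown))
    stop("unknown locus '", tab$locus[unknown[[1]]], "' at line ",
         unknown[[1]] + 1L, " of ", path)
  h <- suppressWarnings(as.numeric(tab$height_raw))
  badh <- which(nzchar(tab$height_raw) & is.na(h))
  if (length(badh))
    stop("non-numeric height at line ", badh[[1]] + 1L, " of ", path)
  negh <- which(!is.na(h) & h < 0)
  if (length(negh))
    stop("negative height at line ", negh[[1]] + 1L, " of ", path)
  tab$height <- h
  ids <- unique(tab$sample_id)
  lapply(ids, function(id) {
    rows <- tab[tab$sample_id == id, c("locus", "allele", "height")]
    s <- if (!is.null(sex) && id %in% names(sex)) sex[[id]] else infer_sex(id)
    str_profile(id, rows, sex = s, panel = panel)
  })
}

infer_sex <- function(sample_id) {
  if (startsWith(sample_id, "M")) "male"
  else if (startsWith(sample_id, "F")) "female"
  else "unknown"
}

#' Write STR profiles as a genotype table
#'
#' Inverse of \code{\link{read_profiles}}: \code{read_profiles(write_profiles(x))}
#' recovers the same profiles up to row order.
#'
#' @param profiles List of \code{str_profile} (or a single profile).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "str_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (!nrow(p$calls)) return(character())
    h <- ifelse(is.na(p$calls$height), "",
                format(p$calls$height, trim = TRUE, scientific = FALSE))
    paste(p$sample_id, p$calls$locus, p$calls$allele, h, sep = ",")
  })
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("sample_id,locus,allele,height", unlist(rows)), con)
  invisible(path)
}
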