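# Locus catalogue for the PowerPlex Fusion 6C multiplex: 23 autosomal STRs,
# 3 Y-STRs and amelogenin. Locus names are the canonical printed forms and
# are compared case-sensitively throughout.

.FUSION6C_AUTOSOMAL <- c(
  "D3S1358", "D1S1656", "D2S441", "D10S1248", "D13S317", "Penta E",
  "D16S539", "D18S51", "D2S1338", "CSF1PO", "Penta D",
  "TH01", "vWA", "D21S11", "D7S820", "D5S818", "TPOX",
  "D8S1179", "D12S391", "D19S433", "SE33", "D22S1045", "FGA"
)
.FUSION6C_Y <- c("DYS391", "DYS576", "DYS570")
.AMELOGENIN <- "Amelogenin"

#' Fusion 6C locus panel
#'
#' Returns the fixed 27-locus catalogue of the PowerPlex Fusion 6C multiplex:
#' 23 autosomal STR loci, three Y-STR loci (male-only) and the amelogenin
#' sex marker. All allele counting in this package is restricted to the
#' autosomal loci; Y-STR and amelogenin calls are carried along but never
#' enter expected/detected/drop-in tallies.
#'
#' @return An object of class \code{str_panel}: a data frame with columns
#'   \code{locus} (character) and \code{kind} (one of \code{"autosomal"},
#'   \code{"y_str"}, \code{"amelogenin"}).
#' @examples
#' p <- fusion6c_panel()
#' table(p$kind)
#' @export
fusion6c_panel <- function() {
  panel <- data.frame(
    locus = c(.FUSION6C_AUTOSOMAL, .FUSION6C_Y, .AMELOGENIN),
    kind = c(rep("autosomal", length(.FUSION6C_AUTOSOMAL)),
             rep("y_str", length(.FUSION6C_Y)),
             "amelogenin"),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("str_panel", "data.frame")
  panel
}

#' Loci of a panel, optionally restricted by kind
#'
#' @param panel An \code{str_panel}.
#' @param kind Optional character vector of kinds to keep
#'   (\code{"autosomal"}, \code{"y_str"}, \code{"amelogenin"}).
#' @return Character vector of locus names, in panel order.
#' @export
panel_loci <- function(panel, kind = NULL) {
  stopifnot(inherits(panel, "str_panel"))
  if (is.null(kind)) return(panel$locus)
  panel$locus[panel$kind %in% kind]
}

#' @export
print.str_panel <- function(x, ...) {
  cat(sprintf("STR panel: %d loci (%d autosomal, %d Y-STR, %d amelogenin)\n",
              nrow(x), sum(x$kind == "autosomal"), sum(x$kind == "y_str"),
              sum(x$kind == "amelogenin")))
  invisible(x)
}
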