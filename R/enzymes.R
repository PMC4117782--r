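#' Restriction enzyme definitions
#'
#' An enzyme is described by its recognition site on the top strand and the
#' offset, in bases from the start of the site, at which the top strand is
#' cut. Only the cut coordinate matters downstream: fragment boundaries are
#' taken at top-strand cut positions and sticky-end geometry is ignored.
#'
#' Built-in enzymes: `EcoRI` (G^AATTC), `MseI` (T^TAA), `DpnII` (^GATC).
#'
#' @param name Enzyme name. Either one of the built-ins, or any label when
#'   `site` is supplied.
#' @param site Recognition site, a DNA string over A/C/G/T, length >= 4.
#'   Omit to look up a built-in enzyme.
#' @param cut_offset Integer offset (>= 0, <= site length) from the site
#'   start to the top-strand cut.
#' @return An object of class `enzyme`: a list with `name`, `site`,
#'   `cut_offset`.
#' @examples
#' enzyme("EcoRI")
#' enzyme("HindIII", site = "AAGCTT", cut_offset = 1)
#' @export
enzyme <- function(name, site = NULL, cut_offset = NULL) {
  if (is.null(site)) {
    hit <- .enzyme_builtins[[name]]
    if (is.null(hit)) {
      stop("unknown enzyme '", name, "'; built-ins are: ",
           paste(names(.enzyme_builtins), collapse = ", "),
           ". Supply `site` and `cut_offset` for a custom enzyme.",
           call. = FALSE)
    }
    site <- hit$site
    cut_offset <- hit$cut_offset
  }
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site) || nchar(site) < 4L) {
    stop("recognition site must be a DNA string over {A,C,G,T} of length >= 4",
         call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must be an integer in [0, site length]", call. = FALSE)
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "enzyme")
}

.enzyme_builtins <- list(
  EcoRI = list(site = "GAATTC", cut_offset = 1L),
  MseI  = list(site = "TTAA",   cut_offset = 1L),
  DpnII = list(site = "GATC",   cut_offset = 0L)
)

#' @export
print.enzyme <- function(x, ...) {
  cut_site <- paste0(substr(x$site, 1, x$cut_offset), "^",
                     substr(x$site, x$cut_offset + 1, nchar(x$site)))
  cat("<enzyme> ", x$name, " (", cut_site, ")\n", sep = "")
  invisible(x)
}

as_enzyme <- function(x) {
  if (inherits(x, "enzyme")) x else enzyme(x)
}
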