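#' Parse a FoodEx2 code string
#'
#' A FoodEx2 code is a mandatory base (list) term, optionally followed by a
#' sequence of facet descriptors. The canonical form separates the base term
#' from the facets with a hashtag and the facets from each other with dollar
#' signs, e.g. \code{"A03BG#F09.A0EXH$F10.A077L$F21.A07SE"}. Codes also occur
#' in the wild with the first facet attached directly with a dollar sign
#' (\code{"A009Q$F14.A07GX"}); both dialects are accepted on input, and
#' \code{\link{format_foodex2}} always emits the canonical hashtag form.
#'
#' @param code_string A single non-empty code string.
#' @return An object of class \code{"foodex2_code"}: a list with elements
#'   \code{base_term} (character scalar) and \code{facets} (data.frame with
#'   columns \code{facet_group}, \code{descriptor}, zero rows when the code
#'   has no facets). Facet order is preserved as given.
#' @examples
#' parse_foodex2("A03BG#F09.A0EXH$F10.A077L$F21.A07SE")
#' parse_foodex2("A041R")
#' parse_foodex2("A009Q$F14.A07GX")
#' @seealso [format_foodex2()]
#' @export
parse_foodex2 <- function(code_string) {
  if (!is.character(code_string) || length(code_string) != 1L ||
      is.na(code_string) || !nzchar(code_string)) {
    stop("`code_string` must be a single non-empty string", call. = FALSE)
  }
  # split base from facet block on the first '#' or, failing that, the first '$'
  if (grepl("#", code_string, fixed = TRUE)) {
    pieces <- strsplit(code_string, "#", fixed = TRUE)[[1L]]
    if (length(pieces) > 2L) {
      stop("malformed code (multiple '#'): ", code_string, call. = FALSE)
    }
    base <- pieces[1L]
    facet_block <- if (length(pieces) == 2L) pieces[2L] else ""
  } else {
    dollar <- regexpr("$", code_string, fixed = TRUE)
    if (dollar > 0L) {
      base <- substr(code_string, 1L, dollar - 1L)
      facet_block <- substr(code_string, dollar + 1L, nchar(code_string))
    } else {
      base <- code_string
      facet_block <- ""
    }
  }
  if (!grepl("^[A-Za-z0-9]+$", base)) {
    stop("malformed base term: '", base, "'", call. = FALSE)
  }
  facets <- empty_facets()
  if (nzchar(facet_block)) {
    segments <- strsplit(facet_block, "$", fixed = TRUE)[[1L]]
    parsed <- lapply(segments, parse_facet_segment)
    facets <- do.call(rbind, parsed)
  }
  new_foodex2_code(base, facets)
}

parse_facet_segment <- function(segment) {
  if (!grepl(".", segment, fixed = TRUE)) {
    stop("malformed facet segment (missing '.'): '", segment, "'",
         call. = FALSE)
  }
  dot <- regexpr(".", segment, fixed = TRUE)
  group <- substr(segment, 1L, dot - 1L)
  descriptor <- substr(segment, dot + 1L, nchar(segment))
  if (!grepl("^F[0-9]+$", group)) {
    stop("malformed facet group (expected F + digits): '", segment, "'",
         call. = FALSE)
  }
  if (!grepl("^[A-Za-z0-9]+$", descriptor)) {
    stop("malformed facet descriptor: '", segment, "'", call. = FALSE)
  }
  data.frame(facet_group = group, descriptor = descriptor,
             stringsAsFactors = FALSE)
}

empty_facets <- function() {
  data.frame(facet_group = character(0), descriptor = character(0),
             stringsAsFactors = FALSE)
}

new_foodex2_code <- function(base_term, facets) {
  structure(list(base_term = base_term, facets = facets),
            class = "foodex2_code")
}

#' Serialize a FoodEx2 code to its canonical string form
#'
#' Emits the base term, then a hashtag if and only if facets are present,
#' with facets joined by dollar signs.
#'
#' @param code A \code{"foodex2_code"} object from [parse_foodex2()].
#' @return A single character string. \code{parse_foodex2(format_foodex2(x))}
#'   reproduces \code{x} for any valid code.
#' @examples
#' format_foodex2(parse_foodex2("A009Q$F14.A07GX"))  # "A009Q#F14.A07GX"
#' @export
format_foodex2 <- function(code) {
  stopifnot(inherits(code, "foodex2_code"))
  if (nrow(code$facets) == 0L) {
    return(code$base_term)
  }
  paste0(code$base_term, "#",
         paste(code$facets$facet_group, code$facets$descriptor,
               sep = ".", collapse = "$"))
}

#' @export
print.foodex2_code <- function(x, ...) {
  cat("<FoodEx2 code>", format_foodex2(x), "\n")
  cat("  base term:", x$base_term, "\n")
  if (nrow(x$facets)) {
    cat("  facets:   ",
        paste(x$facets$facet_group, x$facets$descriptor,
              sep = ".", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.foodex2_code <- function(x, ...) format_foodex2(x)
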