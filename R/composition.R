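#' Elemental compositions
#'
#' An `elem_comp` is a named integer vector of non-negative atom counts over
#' the elements C, H, N, O, P, Na, K — the currency of every mass computation
#' in the package.  Addition and subtraction are element-wise; subtraction
#' that would drop any count below zero is an error.
#'
#' @param ... Named atom counts, e.g. `elem_comp(C = 10, H = 14, N = 5, O = 7, P = 1)`,
#'   or a single named numeric vector.
#' @return An `elem_comp` object.
#' @export
#' @examples
#' amp <- elem_comp(C = 10, H = 14, N = 5, O = 7, P = 1)
#' amp + elem_comp(C = 1, H = 2)
elem_comp <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) && !is.null(names(args[[1]]))) {
    x <- args[[1]]
  } else {
    x <- unlist(args)
  }
  full <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(x)) {
    bad <- setdiff(names(x), .ELEMENTS)
    if (length(bad)) {
      stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(x < 0) || any(x != round(x))) {
      stop("atom counts must be non-negative integers", call. = FALSE)
    }
    full[names(x)] <- as.integer(round(x))
  }
  structure(full, class = "elem_comp")
}

.as_comp_vec <- function(x) {
  full <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  full[names(x)] <- as.integer(x)
  full
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    stop("operation '", .Generic, "' not defined for elem_comp", call. = FALSE)
  }
  a <- .as_comp_vec(unclass(e1))
  b <- .as_comp_vec(unclass(e2))
  if (.Generic == "==") {
    return(all(a == b))
  }
  out <- get(.Generic)(a, b)
  if (any(out < 0)) {
    stop("composition subtraction would yield a negative atom count",
         call. = FALSE)
  }
  structure(out, class = "elem_comp")
}

#' @export
format.elem_comp <- function(x, ...) {
  v <- unclass(x)
  v <- v[v > 0]
  if (!length(v)) return("(empty)")
  paste0(names(v), ifelse(v > 1, v, ""), collapse = "")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Mass of an elemental composition
#'
#' @param comp An [elem_comp()].
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return Mass in daltons.
#' @export
comp_mass <- function(comp, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  v <- .as_comp_vec(unclass(comp))
  tab <- if (kind == "monoisotopic") .MONO_MASS else .AVG_MASS
  sum(v * tab[names(v)])
}
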