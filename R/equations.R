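#' Parse a reaction equation string
#'
#' Equations use the tabular dialect `"2 A[c] + B[c] -> C[m]"`: species
#' carry their compartment in square brackets, `"->"` marks an irreversible
#' and `"<->"` a reversible reaction, and either side may be empty (boundary
#' reactions, e.g. `"co2[e] ->"` for an export or `"-> co2[e]"` for an
#' import). Coefficients may be decimals or fractions (`"3/2"`).
#'
#' @param eq equation string.
#' @return list with `stoich` (named numeric, negative = consumed) and
#'   `reversible` (logical).
#' @examples
#' parseEquation("2 A[c] + B[c] -> C[m]")
#' parseEquation("-> co2[e]")
#' @export
parseEquation <- function(eq) {
  eq <- trimws(eq)
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<->", fixed = TRUE)[[1]]
           else strsplit(eq, "->", fixed = TRUE)[[1]]
  if (!grepl("->", eq, fixed = TRUE))
    stop("malformed equation (no arrow): '", eq, "'")
  lhs <- if (length(sides) >= 1L) sides[1] else ""
  rhs <- if (length(sides) >= 2L) sides[2] else ""
  st <- c(.parseSide(lhs, -1, eq), .parseSide(rhs, +1, eq))
  if (length(st) == 0L)
    stop("malformed equation (no species): '", eq, "'")
  ## merge species appearing on both sides
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  list(stoich = structure(as.numeric(st), names = names(st)),
       reversible = rev)
}

.parseSide <- function(side, sign, eq) {
  side <- trimws(side)
  if (side == "") return(numeric())
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  terms <- terms[terms != ""]
  out <- numeric(length(terms))
  ids <- character(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i],
                    regexec("^(?:([0-9]+(?:\\.[0-9]+)?(?:/[0-9]+)?)\\s+)?(\\S+)$",
                            terms[i]))[[1]]
    if (length(m) != 3L)
      stop("malformed equation term '", terms[i], "' in '", eq, "'")
    coef <- if (m[2] == "") 1 else .parseCoefficient(m[2])
    out[i] <- sign * coef
    ids[i] <- m[3]
  }
  structure(out, names = ids)
}

.parseCoefficient <- function(x) {
  if (grepl("/", x, fixed = TRUE)) {
    pq <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
    pq[1] / pq[2]
  } else as.numeric(x)
}

#' Format a stoichiometry as an equation string
#'
#' Inverse of [parseEquation()] up to term order (species are emitted in the
#' order of `stoich`). Coefficients are emitted as decimals.
#'
#' @param stoich named numeric vector (negative = consumed).
#' @param reversible emit `"<->"` instead of `"->"`.
#' @return equation string.
#' @export
formatEquation <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    if (length(v) == 0L) return("")
    paste(vapply(seq_along(v), function(i) {
      coef <- unname(abs(v[i]))
      if (isTRUE(all.equal(coef, 1))) names(v)[i]
      else paste(format(coef, digits = 15, scientific = FALSE, trim = TRUE),
                 names(v)[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(stoich[stoich < 0])
  rhs <- fmt(stoich[stoich > 0])
  arrow <- if (reversible) "<->" else "->"
  trimws(paste(lhs, arrow, rhs))
}
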