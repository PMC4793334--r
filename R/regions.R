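#' Canonical region registry
#'
#' The analysis partitions the American black duck range into seven fixed
#' regions: four breeding regions (NW Canada, SW Canada, NE Canada,
#' SE Canada) and three wintering regions (N Atlantic, S Atlantic,
#' Interior). The registry is closed: every operation in the package
#' validates region labels against it and refuses to create new ones.
#'
#' `north_rank` is a coarse south-to-north ordering used only for the
#' "northward movement" derived statistic: S Atlantic < {Interior,
#' N Atlantic} < {SE Canada, SW Canada} < {NE Canada, NW Canada}. A bird
#' has "moved north" when its recovery region has a strictly larger rank
#' than its banding region. The ordering is overridable via the
#' `north_rank` argument of [derivedSummaries()].
#'
#' @return A data.frame with columns `region` (character), `role`
#'   (`"breeding"` or `"wintering"`) and `north_rank` (integer), one row
#'   per region, in canonical order (breeding first, west to east, then
#'   wintering).
#' @examples
#' regionRegistry()
#' @export
regionRegistry <- function() {
  data.frame(
    region = c("NW Canada", "SW Canada", "NE Canada", "SE Canada",
               "N Atlantic", "S Atlantic", "Interior"),
    role = c(rep("breeding", 4L), rep("wintering", 3L)),
    north_rank = c(4L, 3L, 4L, 3L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Canonical region names
#'
#' @param role Optional filter: `"breeding"` or `"wintering"`.
#' @return Character vector of canonical region names in registry order.
#' @examples
#' regionNames()
#' regionNames("wintering")
#' @export
regionNames <- function(role = NULL) {
  reg <- regionRegistry()
  if (!is.null(role)) {
    role <- match.arg(role, c("breeding", "wintering"))
    reg <- reg[reg$role == role, , drop = FALSE]
  }
  reg$region
}

N_REGIONS <- 7L

# Normalize free-text region labels to canonical names; unknown labels
# come back NA (callers decide whether that is fatal).
normalizeRegion <- function(x) {
  canon <- regionNames()
  # tolerate case and whitespace variation, plus the common period-free /
  # abbreviated forms of BBL-style exports
  key <- function(s) gsub("[^a-z]", "", tolower(s))
  lookup <- stats::setNames(canon, key(canon))
  extras <- c(
    northatlantic = "N Atlantic", southatlantic = "S Atlantic",
    northwestcanada = "NW Canada", southwestcanada = "SW Canada",
    northeastcanada = "NE Canada", southeastcanada = "SE Canada"
  )
  lookup <- c(lookup, extras)
  out <- unname(lookup[key(as.character(x))])
  out
}

assertRegions <- function(x, what = "region") {
  norm <- normalizeRegion(x)
  bad <- !is.na(x) & x != "" & is.na(norm)
  if (any(bad)) {
    stop("unknown ", what, " label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (the 7-region registry is closed)", call. = FALSE)
  }
  norm
}
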