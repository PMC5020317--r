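#' OSGB grid-reference parsing and 1-km cell (monad) arithmetic
#'
#' Alphanumeric British National Grid references are resolved to south-west
#' corner coordinates in metres on the OSGB36/BNG plane, plus the edge length
#' of the referenced square. The letter pair is decoded with the standard
#' 25-letter (I omitted) false-origin scheme; tetrad (2 km) references use the
#' DINTY suffix convention. No datum transformation is performed.
#'
#' @name osgb
NULL

# second-position letters: 5x5 grid, A top-left, I skipped
.osgb_letters <- LETTERS[-9]

# first-position letters admitted for the GB grid (500-km squares)
.osgb_first <- c("H", "J", "N", "O", "S", "T")

# DINTY tetrad letters: columns bottom-up, O skipped
.dinty_letters <- LETTERS[-15]

.letter_index <- function(ch) {
  # 0-based index in the 25-letter scheme (I skipped)
  i <- match(ch, .osgb_letters)
  i - 1L
}

#' Parse OSGB grid references
#'
#' @param gridref Character vector of grid references, e.g. `"TQ3280"`,
#'   `"TQ328803"`, `"TQ"`, or a tetrad such as `"TQ17U"`. Internal whitespace
#'   and case are ignored.
#'
#' @return A tibble with one row per input: `gridref`, `easting`, `northing`
#'   (metres, SW corner) and `precision_m` (edge length of the square: 100000,
#'   10000, 1000, 100, 10, 1, or 2000 for tetrads).
#'
#' @details Malformed references (invalid letters, odd digit counts, invalid
#'   tetrad letters) raise an error naming the offending token.
#'
#' @examples
#' parse_gridref(c("TQ3280", "TQ328803", "TQ"))
#' @export
parse_gridref <- function(gridref) {
  stopifnot(is.character(gridref))
  ref <- toupper(gsub("[[:space:]]", "", gridref))
  n <- length(ref)
  easting <- northing <- precision <- numeric(n)
  for (i in seq_len(n)) {
    r <- ref[i]
    if (!grepl("^[A-Z]{2}", r)) {
      stop("malformed grid reference '", gridref[i],
           "': expected two 100-km square letters", call. = FALSE)
    }
    l1 <- substr(r, 1, 1)
    l2 <- substr(r, 2, 2)
    if (!l1 %in% .osgb_first) {
      stop("malformed grid reference '", gridref[i], "': '", l1,
           "' is not a valid OSGB 500-km letter", call. = FALSE)
    }
    if (!l2 %in% .osgb_letters) {
      stop("malformed grid reference '", gridref[i], "': '", l2,
           "' is not a valid OSGB letter", call. = FALSE)
    }
    i1 <- .letter_index(l1)
    i2 <- .letter_index(l2)
    e100 <- ((i1 %% 5L) - 2L) %% 5L * 5L + (i2 %% 5L)
    n100 <- (19L - (i1 %/% 5L) * 5L) - (i2 %/% 5L)
    rest <- substr(r, 3, nchar(r))
    tetrad <- ""
    if (nchar(rest) > 0 && grepl("[A-Z]$", rest)) {
      tetrad <- substr(rest, nchar(rest), nchar(rest))
      rest <- substr(rest, 1, nchar(rest) - 1)
    }
    if (!grepl("^[0-9]*$", rest)) {
      stop("malformed grid reference '", gridref[i],
           "': unexpected characters '", rest, "'", call. = FALSE)
    }
    nd <- nchar(rest)
    if (nd %% 2L != 0L || nd > 10L) {
      stop("malformed grid reference '", gridref[i], "': digit part '",
           rest, "' must have an even count of 0-10 digits", call. = FALSE)
    }
    half <- nd %/% 2L
    de <- if (half > 0) as.numeric(substr(rest, 1, half)) else 0
    dn <- if (half > 0) as.numeric(substr(rest, half + 1, nd)) else 0
    unit <- 10^(5 - half)
    e <- e100 * 100000 + de * unit
    nn <- n100 * 100000 + dn * unit
    prec <- unit
    if (nzchar(tetrad)) {
      if (half != 1L) {
        stop("malformed grid reference '", gridref[i],
             "': tetrad letter requires a two-digit 10-km reference",
             call. = FALSE)
      }
      ti <- match(tetrad, .dinty_letters)
      if (is.na(ti)) {
        stop("malformed grid reference '", gridref[i], "': '", tetrad,
             "' is not a valid DINTY tetrad letter", call. = FALSE)
      }
      ti <- ti - 1L
      e <- e + (ti %/% 5L) * 2000
      nn <- nn + (ti %% 5L) * 2000
      prec <- 2000
    }
    easting[i] <- e
    northing[i] <- nn
    precision[i] <- prec
  }
  tibble::tibble(gridref = gridref, easting = easting,
                 northing = northing, precision_m = precision)
}

#' 1-km cell identifier for OSGB coordinates
#'
#' Floors coordinates to the kilometre and returns the four-digit grid
#' reference of the containing monad, e.g. `monad_of(532800, 180300)` is
#' `"TQ3280"`. Idempotent for coordinates already on a 1-km corner.
#'
#' @param easting,northing Numeric vectors of OSGB coordinates in metres.
#'   Must lie within the GB grid (easting in \[0, 1e6), northing in
#'   \[0, 1.5e6)).
#' @return Character vector of monad grid references.
#' @export
monad_of <- function(easting, northing) {
  stopifnot(is.numeric(easting), is.numeric(northing),
            length(easting) == length(northing))
  bad <- easting < 0 | easting >= 1e6 | northing < 0 | northing >= 1.5e6 |
    !is.finite(easting) | !is.finite(northing)
  if (any(bad)) {
    stop("coordinates out of OSGB range: (", easting[which(bad)[1]], ", ",
         northing[which(bad)[1]], ")", call. = FALSE)
  }
  e500 <- easting %/% 5e5
  n500 <- northing %/% 5e5
  # first letter by 500-km block: cols S,T / N,O / H,J bottom-up
  first <- matrix(c("S", "T", "N", "O", "H", "J"), nrow = 2)[
    cbind(e500 + 1, n500 + 1)]
  e100 <- (easting %% 5e5) %/% 1e5
  n100 <- (northing %% 5e5) %/% 1e5
  idx2 <- 5 * (4 - n100) + e100
  second <- .osgb_letters[idx2 + 1]
  ekm <- (easting %% 1e5) %/% 1000
  nkm <- (northing %% 1e5) %/% 1000
  paste0(first, second, sprintf("%02d", ekm), sprintf("%02d", nkm))
}

#' SW-corner coordinates of a monad identifier
#'
#' Inverse of [monad_of()] for 1-km references; thin wrapper over
#' [parse_gridref()] that checks the reference really is at 1-km precision.
#'
#' @param monad Character vector of 1-km grid references.
#' @return A tibble with `easting`, `northing` (metres).
#' @export
monad_coords <- function(monad) {
  p <- parse_gridref(monad)
  if (any(p$precision_m != 1000)) {
    stop("not a 1-km grid reference: '",
         monad[which(p$precision_m != 1000)[1]], "'", call. = FALSE)
  }
  p[c("easting", "northing")]
}
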