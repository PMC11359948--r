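# 8-neighbour offsets for the LBP code, (row, col). p = 0 is the east
# neighbour and p increases counter-clockwise (north = decreasing row).
LBP_OFFSETS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                    c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

# Codes whose circular 8-bit representation has at most two 0<->1
# transitions ("uniform patterns"); there are exactly 58 of them.
lbp_uniform_codes <- local({
  codes <- NULL
  function() {
    if (is.null(codes)) {
      tr <- vapply(0:255, function(code) {
        b <- as.integer(intToBits(code))[1:8]
        sum(b != c(b[-1], b[1]))
      }, integer(1))
      codes <<- which(tr <= 2) - 1L
    }
    codes
  }
})

# Map raw code (0..255) -> histogram bin (1..59). Uniform codes occupy bins
# 1..58 in ascending code order; all non-uniform codes share bin 59.
lbp_bin_lookup <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      lut <- rep(59L, 256)
      lut[lbp_uniform_codes() + 1L] <- seq_len(58L)
    }
    lut
  }
})

#' Local binary pattern code map
#'
#' Computes the classic 8-neighbour LBP code of every interior pixel:
#' `code = sum_p 2^p * s(i_p - i_c)` with `s(x) = 1` if `x > 0` and `0`
#' otherwise (ties count as 0). Neighbour `p = 0` is the east neighbour and
#' `p` increases counter-clockwise. The 1-pixel image border has no full
#' neighbourhood and is excluded rather than padded.
#'
#' @param image Numeric matrix of grayscale intensities, at least 3x3.
#' @return An object of class `lbp_code_map` whose `$codes` element is an
#'   integer matrix (`nrow(image)-2` by `ncol(image)-2`) of codes in 0..255.
#' @export
lbp_code_map <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3)
    stop("degenerate image: LBP needs at least a 3x3 grid", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  rows <- 2:(h - 1); cols <- 2:(w - 1)
  ctr <- image[rows, cols, drop = FALSE]
  codes <- matrix(0L, h - 2, w - 2)
  for (p in 0:7) {
    o <- LBP_OFFSETS[[p + 1]]
    nb <- image[rows + o[1], cols + o[2], drop = FALSE]
    codes <- codes + (nb > ctr) * bitwShiftL(1L, p)
  }
  structure(list(codes = codes), class = "lbp_code_map")
}

#' 59-bin uniform-pattern histogram of an LBP code map
#'
#' The 58 uniform codes (at most two circular bit transitions) get one bin
#' each, in ascending code order; every non-uniform code is pooled into the
#' 59th bin. Frequencies are normalised by the number of valid (interior)
#' pixels and therefore sum to one.
#'
#' @param code_map An [lbp_code_map()].
#' @return Object of class `lbp_histogram`: list with `$bins` (numeric, 59,
#'   summing to 1).
#' @export
uniform_histogram <- function(code_map) {
  stopifnot(inherits(code_map, "lbp_code_map"))
  codes <- code_map$codes
  if (length(codes) < 1)
    stop("code map has no valid pixels", call. = FALSE)
  bins <- tabulate(lbp_bin_lookup()[as.vector(codes) + 1L], nbins = 59L)
  structure(list(bins = bins / length(codes)), class = "lbp_histogram")
}

#' LBP feature block for one modality of an eye record
#'
#' Runs [lbp_code_map()] + [uniform_histogram()] on the three projection
#' slabs (FULL, ILM-OPL, OPL-BM) of the given modality and concatenates the
#' histograms into 177 named scalars
#' `"<modality>_<layer>_LBP1"` ... `"<modality>_<layer>_LBP59"`.
#'
#' @param record An [eye_record()].
#' @param modality `"OCT"` or `"OCTA"`.
#' @return Named numeric vector of length 177.
#' @export
lbp_feature_block <- function(record, modality) {
  modality <- match.arg(modality, MODALITIES)
  out <- numeric(0)
  for (layer in LAYERS) {
    key <- paste0(modality, "_", layer)
    img <- record$projections[[key]]
    if (is.null(img))
      stop("incomplete record '", record$eye_id, "': missing projection ",
           key, call. = FALSE)
    hist <- uniform_histogram(lbp_code_map(img))
    v <- hist$bins
    names(v) <- paste0(modality, "_", layer, "_LBP", 1:59)
    out <- c(out, v)
  }
  out
}
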