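#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.5 -> 1`), the convention used by
#' clinical tables, as opposed to the IEEE banker's rounding of [round()].
#' Used only for display/report formatting; internal statistics are never
#' rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(90.455, 2)  # 90.46
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# ceiling robust to representation noise: values within eps of an integer
# are treated as that integer before rounding up
ceil_eps <- function(x, eps = 1e-9) as.integer(ceiling(x - eps))

# tiny FNV-1a string hash for config provenance stamps (hex string);
# not cryptographic, just a stable run identifier
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor on the low byte only (codepoints < 256 after utf8ToInt of each
    # byte-sized char; larger codepoints fold onto the low byte first)
    h <- h - h %% 256 + bitwXor(h %% 256, b %% 256)
    # multiply by the FNV prime mod 2^32 in two 16-bit halves so the
    # intermediate products stay inside double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_wsigrid <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "wsigrid_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
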