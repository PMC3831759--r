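# Internal numerical helpers shared across modules.

# Tabulated Gauss-Legendre rules on [-1, 1]; the element routines only ever
# need orders 1..5.  The brute-force verification oracle deliberately does
# NOT use this table (it calls pracma::gaussLegendre) so that the two code
# paths stay independent.
gauss_rule <- function(n) {
  switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(
      x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
      w = c(5, 8, 5) / 9
    ),
    "4" = list(
      x = c(-0.8611363115940526, -0.3399810435848563,
            0.3399810435848563, 0.8611363115940526),
      w = c(0.3478548451374538, 0.6521451548625461,
            0.6521451548625461, 0.3478548451374538)
    ),
    "5" = list(
      x = c(-0.9061798459386640, -0.5384693101056831, 0,
            0.5384693101056831, 0.9061798459386640),
      w = c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
            0.4786286704993665, 0.2369268850561891)
    ),
    stop("gauss_rule: order must be between 1 and 5", call. = FALSE)
  )
}

#' Parse a pressure value with an optional unit suffix
#'
#' Configuration files may give pressures as plain numbers (pascal) or as
#' strings with an explicit unit: `"Pa"`, `"kPa"`, `"MPa"` or `"bar"`.
#' Everything is normalised to pascal internally.
#'
#' @param x A number (taken as Pa) or a string such as `"8 kPa"` or `"2bar"`.
#' @return Pressure in pascal.
#' @examples
#' parse_pressure("8 kPa")
#' parse_pressure(101325)
#' @export
parse_pressure <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop("pressure must be a number (Pa) or a single string with a unit",
         call. = FALSE)
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*(Pa|kPa|MPa|bar)\\s*$", x))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse pressure '%s' (use Pa, kPa, MPa or bar)", x),
         call. = FALSE)
  val <- as.numeric(m[2])
  if (is.na(val)) stop(sprintf("cannot parse pressure '%s'", x), call. = FALSE)
  val * switch(m[3], Pa = 1, kPa = 1e3, MPa = 1e6, bar = 1e5)
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits.  Used to give
# run configurations a short reproducible digest without external deps.
fnv1a_hex <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits; keep h a double (32-bit
    # unsigned values overflow R integers)
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619, via 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Canonical digest of an arbitrary plain-list configuration object.
config_digest <- function(x) {
  fnv1a_hex(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                             null = "null", force = TRUE))
}

# Classed error constructors so the command-line wrapper can map error
# families onto exit codes (2 = configuration, 3 = solver).
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cervodil_config_error", "error")))
}
stop_solver <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cervodil_solver_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row (margin = 1) or column (margin = 2) maxima of |A| for a sparse
# matrix, without densifying.  Zero rows/columns get 1 (harmless scaling).
sparse_margin_absmax <- function(A, margin) {
  Tt <- methods::as(A, "TsparseMatrix")
  idx <- if (margin == 1) Tt@i + 1L else Tt@j + 1L
  n <- dim(A)[margin]
  out <- rep(0, n)
  if (length(idx)) {
    agg <- tapply(abs(Tt@x), idx, max)
    out[as.integer(names(agg))] <- agg
  }
  out[out == 0] <- 1
  out
}
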