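# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sparc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Shortest angular distance between two gantry angles
#'
#' Distance travelled along the shorter of the two rotation directions,
#' in degrees, always in `[0, 180]`.
#'
#' @param a,b Gantry angles in degrees (any real value; reduced mod 360).
#' @return Non-negative angular distance in degrees.
#' @export
angular_distance <- function(a, b) {
  abs(((b - a + 180) %% 360) - 180)
}

# TRUE when angle (deg, any representative) lies inside sector [from, to]
# walked from `from` increasing mod 360; sectors may wrap through 0.
angle_in_sector <- function(angle, from, to) {
  a <- angle %% 360
  f <- from %% 360
  t <- to %% 360
  if (f <= t) a >= f & a <= t else a >= f | a <= t
}

# canonical fixed-format number for plan serialization: 6 decimals
canonical_num <- function(x) {
  s <- sprintf("%.6f", x)
  # normalize negative zero
  s[s == "-0.000000"] <- "0.000000"
  s
}
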