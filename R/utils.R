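# internal helpers shared across modules

#' Environmental predictor schema
#'
#' Column names of the environmental predictors a site table may carry:
#' `Forest`, `Shrub`, `Herb`, `Bared` (vegetation/bare covers, percent),
#' `Lnum` (land-cover patch count), `Bar` (gravel-bar area), `Width`
#' (channel width, m), `Sinuosity` (channel over straight-line length,
#' >= 1) and `H_SD` (vegetation-height standard deviation, m).
#'
#' @format character vector of length 9.
#' @export
rip_env_vars <- c("Forest", "Shrub", "Herb", "Bared", "Lnum", "Bar",
                  "Width", "Sinuosity", "H_SD")
rip_pct_vars <- c("Forest", "Shrub", "Herb", "Bared")

# derive a reproducible sub-seed for a named component from one master seed;
# keeps every derived seed a valid 32-bit integer
rip_substream <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(tree = 101L, traits = 211L, sites = 307L, community = 401L,
            status = 503L, null = 601L, perm = 701L, misc = 811L)
  off <- offs[[component]]
  as.integer((abs(as.numeric(seed)) * 48271 + off * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rip_stop <- function(...) stop(..., call. = FALSE)
rip_warn <- function(...) warning(..., call. = FALSE)
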