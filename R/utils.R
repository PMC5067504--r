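#' Genome-wide significance threshold
#'
#' The conventional genome-wide significance level for single-SNP association
#' tests, 5e-8.
#'
#' @export
GENOME_WIDE_SIG <- 5e-8

# Validation helpers --------------------------------------------------------

stop_netsig <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "netsig_error")))
}

assert_that <- function(cond, msg, class = "netsig_invalid_input") {
  if (!isTRUE(cond)) stop_netsig(msg, class)
  invisible(TRUE)
}

assert_prob <- function(p, name = "p", open_zero = FALSE, open_one = FALSE) {
  ok <- is.numeric(p) && !anyNA(p) &&
    all(p >= 0) && all(p <= 1) &&
    (!open_zero || all(p > 0)) && (!open_one || all(p < 1))
  assert_that(ok, sprintf("'%s' must contain probabilities in %s0,1%s",
                          name, if (open_zero) "(" else "[",
                          if (open_one) ")" else "]"))
}

assert_count <- function(x, name, min = 1L) {
  assert_that(is.numeric(x) && length(x) == 1L && !is.na(x) &&
                x >= min && x == floor(x),
              sprintf("'%s' must be a single integer >= %d", name, min))
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' Each simulation stage consumes an independent substream derived from the
#' master seed by a fixed per-stage offset, so regenerating one stage never
#' perturbs another.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return an integer seed below 2^31.
#' @keywords internal
stage_seed <- function(seed, stage) {
  offsets <- c(interactome = 101L, expression = 211L, gwas = 307L,
               annotations = 401L, comorbidity = 503L, discovery = 601L,
               topology = 701L, enrichment = 809L, controls = 907L)
  if (!stage %in% names(offsets)) {
    stop_netsig(sprintf("unknown stage '%s'", stage), "netsig_invalid_input")
  }
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483629)
}

# Upper-case, trim whitespace; shared by all gene-symbol entry points.
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}
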