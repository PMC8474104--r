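#' @keywords internal
"_PACKAGE"

# Genotype codes used throughout: 0 = WT (two intact copies), 1 = heterozygote,
# 2 = deletion homozygote. Copy number at probes inside the deletion is
# 2 - genotype.
GENOTYPE_CODES <- 0:2
GENOTYPE_LABELS <- c("WT", "het", "hom")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_delcall <- function(..., class = "delcall_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_delcall(...)
  invisible(TRUE)
}

assert_prob <- function(x, name) {
  assert_that(is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1),
              sprintf("'%s' must be in [0, 1]", name))
}

# Run code under a fixed RNG seed without touching global RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of sub-seeds from one master seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# argmax with deterministic tie-break: lowest index wins.
argmax_first <- function(x) which(x == max(x))[1L]
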