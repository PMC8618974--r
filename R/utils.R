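#' @useDynLib picuree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pf cor sd rnorm runif rbinom qnorm pnorm approx coef
#'   lm predict complete.cases
#' @importFrom utils read.csv write.csv modifyList
NULL

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("picuree_config_error", "picuree_error")))
}

abort_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("picuree_data_error", "picuree_error")))
}

abort_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("picuree_domain_error", "picuree_error")))
}

#' Path to a bundled data file
#'
#' @param file file name under the package's `extdata` directory
#' @return absolute path
#' @keywords internal
picuree_extdata <- function(file) {
  p <- system.file("extdata", file, package = "picuree")
  if (!nzchar(p)) abort_config("bundled data file not found: %s", file)
  p
}

# run code under a private RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# deterministic child seed derived from a master seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}
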