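# Internal helpers shared across modules: seed derivation, temporary RNG
# scopes, and CSV I/O that carries reproducibility metadata in '#' header
# comment lines.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash of a string, kept exact in double precision and
# reduced mod 2^31 - 1 so it is a valid R integer seed component. Stable
# across sessions and platforms (depends only on UTF-8 code points).
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(as.character(s)))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Child seed = (master seed + hash of a "/"-joined label) mod 2^31 - 1.
# Guarantees per-patient reproducibility independent of generation order.
derive_seed <- function(master_seed, ...) {
  label <- paste(..., sep = "/")
  as.integer((as.numeric(master_seed) + stable_hash(label)) %% 2147483647)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Stationary AR(1) noise: lag-1 correlation `rho`, marginal sd `sd`.
# x_1 ~ N(0, sd); innovations have sd * sqrt(1 - rho^2).
ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  innov <- rnorm(n, mean = 0, sd = sd * sqrt(1 - rho^2))
  innov[1] <- rnorm(1, mean = 0, sd = sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

circarq_meta <- function(seed = NULL, extra = character()) {
  c(paste0("circarq version=", as.character(utils::packageVersion("circarq"))),
    if (!is.null(seed)) paste0("seed=", as.integer(seed)),
    extra)
}

# Short fingerprint of an arbitrary configuration object (for output headers).
config_fingerprint <- function(x) {
  sprintf("%08x", stable_hash(paste(deparse(x), collapse = " ")))
}

write_meta_csv <- function(df, path, meta = character()) {
  con <- file(path, open = "w")
  on.exit(close(con), add = TRUE)
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_meta_csv <- function(path, ...) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
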