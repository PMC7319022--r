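# Shared helpers for the analysis drivers: output locations, a tiny flag
# parser, and run manifests. Each numbered script is a thin narrative driver
# over the jointmark package; all computation lives in R/.

suppressPackageStartupMessages(library(jointmark))

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# --seed 1 --fast ... -> named list; flags without values become TRUE
parse_flags <- function(defaults = list(seed = 1L, fast = TRUE)) {
  args <- commandArgs(trailingOnly = TRUE)
  out <- defaults
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      val <- args[i + 1L]
      out[[key]] <- if (grepl("^-?[0-9.]+$", val)) as.numeric(val) else val
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out$seed <- as.integer(out$seed)
  out
}

write_manifest <- function(dir, config, extra = list()) {
  manifest <- c(list(
    config = config,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("jointmark")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

rhat_summary <- function(fit) {
  list(max_rhat = fit$max_rhat, converged = fit$converged,
       n_chains = fit$settings$n_chains, n_iter = fit$settings$n_iter)
}
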