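# Parse a plain "key = value" text file. Lines starting with '#' and blank
# lines are ignored; values are converted to numeric where possible
# ("inf" maps to Inf).
read_key_values <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("inf", "infinite")) Inf
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
  }
  out
}

#' Read a run configuration file
#'
#' Plain `key = value` text. Recognized keys mirror the constructor
#' arguments: model parameters (`lambda`, `J`, `x0`, `x_max`, `n_grid`),
#' run shape (`q`, `parities`, `B`, `N`, `dedup_tol`, `workers`, `seed`),
#' backend (`mode`, `shots`, `final_shots`, `readout_mitigation`, `zne`,
#' `device_file`), and optimizer settings (`penalty`, `max_iter`,
#' `optimizer`, `f_max_nft`, `reset_interval`, `f_max_refine`, `f_tol`,
#' `retrials`, `rho_beg`). Missing keys fall back to package defaults.
#'
#' @param file Path to the configuration file.
#' @return List with elements `q`, `parities`, `spec`, `batch`,
#'   `deflation`, `refinement`, `backend` ready for [resonance_search()].
#' @export
read_run_config <- function(file) {
  kv <- read_key_values(file)
  pick <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  spec <- model_spec(lambda = pick("lambda", 0.1), J = pick("J", 0.8),
                     x0 = pick("x0", 8), x_max = pick("x_max", 10),
                     n_grid = pick("n_grid", 2^12))
  batch <- batch_config(B = pick("B", 8), N = pick("N", 4),
                        dedup_tol = pick("dedup_tol", 0.8),
                        workers = pick("workers", 1),
                        seed = pick("seed", 1))
  deflation <- deflation_config(penalty = pick("penalty", 100),
                                max_iter = pick("max_iter", 2^9),
                                optimizer = pick("optimizer", "cobyla"),
                                f_max = pick("f_max_nft", 2^11),
                                reset_interval = pick("reset_interval", 32))
  refinement <- refinement_config(f_max = pick("f_max_refine", 2^10),
                                  f_tol = pick("f_tol", 0.05),
                                  retrials = pick("retrials", 3),
                                  rho_beg = pick("rho_beg", 1))
  device <- if (!is.null(kv$device_file)) read_device_model(kv$device_file)
            else if (pick("mode", "exact") == "noisy") device_model()
            else NULL
  backend <- backend_config(mode = pick("mode", "exact"),
                            shots = pick("shots", 1e5),
                            final_shots = pick("final_shots", 1e6),
                            device = device,
                            readout_mitigation = pick("readout_mitigation",
                                                      FALSE),
                            zne = pick("zne", FALSE))
  parities <- pick("parities", "even,odd")
  parities <- trimws(strsplit(parities, ",")[[1]])
  list(q = pick("q", 3), parities = parities, spec = spec, batch = batch,
       deflation = deflation, refinement = refinement, backend = backend)
}
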