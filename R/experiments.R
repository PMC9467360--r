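#' Benchmark trial scenarios
#'
#' The twelve two-armed scenarios used throughout the simulation study:
#' five null scenarios (equal success probabilities, n = 200) and seven
#' alternative scenarios whose trial sizes give 90\% power under equal
#' allocation.
#'
#' @return data frame with columns \code{scenario}, \code{p0}, \code{p1},
#'   \code{n}, \code{hypothesis}.
#' @export
trial_scenarios <- function() {
  out <- data.frame(
    scenario = paste0("S", 1:12),
    p0 = c(0.10, 0.30, 0.50, 0.70, 0.90, 0.10, 0.10, 0.10, 0.40, 0.60, 0.70, 0.80),
    p1 = c(0.10, 0.30, 0.50, 0.70, 0.90, 0.20, 0.30, 0.40, 0.60, 0.90, 0.90, 0.90),
    n  = c(200L, 200L, 200L, 200L, 200L, 526L, 162L, 82L, 254L, 82L, 162L, 526L))
  out$hypothesis <- ifelse(out$p0 == out$p1, "null", "alternative")
  out
}

#' Missingness-probability combinations
#'
#' \code{"paper_16"}: equal missingness in both arms (rates 0 to 0.5 in
#' steps of 0.1), control-arm-only missingness, and experimental-arm-only
#' missingness — 16 unique combinations. \code{"full_grid_36"}: the full
#' 6 x 6 grid of rates.
#'
#' @param type \code{"paper_16"} or \code{"full_grid_36"}.
#' @return data frame with columns \code{pm0}, \code{pm1}, \code{pattern}
#'   (\code{"equal"}, \code{"control"}, \code{"experimental"}).
#' @export
missingness_grid <- function(type = c("paper_16", "full_grid_36")) {
  type <- match.arg(type)
  rates <- seq(0, 0.5, by = 0.1)
  if (type == "full_grid_36") {
    g <- expand.grid(pm0 = rates, pm1 = rates)
    g$pattern <- ifelse(g$pm0 == g$pm1, "equal",
                        ifelse(g$pm1 == 0, "control",
                               ifelse(g$pm0 == 0, "experimental", "mixed")))
    return(g)
  }
  rbind(
    data.frame(pm0 = rates, pm1 = rates, pattern = "equal"),
    data.frame(pm0 = rates[-1], pm1 = 0, pattern = "control"),
    data.frame(pm0 = 0, pm1 = rates[-1], pattern = "experimental"))
}

#' Build a grid of trial configurations
#'
#' Cross-product of scenarios, missingness combinations, allocation rules
#' and imputation settings. Each cell gets a deterministic seed derived from
#' the master seed and the cell's labels, so adding cells never perturbs
#' existing ones, and a default replication count (\code{R_default}, except
#' \code{R_tts} for the computationally heavier tuned Thompson sampling).
#'
#' @param scenarios data frame as from [trial_scenarios()] (any subset).
#' @param missingness data frame as from [missingness_grid()].
#' @param algorithms character vector of rule names.
#' @param imputation character vector: subset of \code{c("off", "mean")}.
#' @param master_seed integer master seed.
#' @param R_default,R_tts replication counts.
#' @param impute_initial initial imputation estimate.
#' @param impute_after_first impute only after the first observed outcome.
#' @return data frame, one row per cell, with all [trial_config()] fields
#'   plus \code{scenario}, \code{pattern}, \code{R} and \code{seed}.
#' @export
build_grid <- function(scenarios = trial_scenarios(),
                       missingness = missingness_grid("paper_16"),
                       algorithms = bandit_policies(),
                       imputation = "off",
                       master_seed = 1L,
                       R_default = 10000L, R_tts = 1000L,
                       impute_initial = 0.5,
                       impute_after_first = FALSE) {
  stopifnot(all(algorithms %in% bandit_policies()),
            all(imputation %in% c("off", "mean")))
  cells <- merge(merge(scenarios, missingness, by = NULL),
                 expand.grid(algorithm = algorithms,
                             imputation = imputation,
                             stringsAsFactors = FALSE), by = NULL)
  cells$R <- ifelse(cells$algorithm == "TTS", R_tts, R_default)
  cells$impute_initial <- impute_initial
  cells$impute_after_first <- impute_after_first
  cells$seed <- vapply(seq_len(nrow(cells)), function(i)
    cell_seed(master_seed, cells$scenario[i], cells$pm0[i], cells$pm1[i],
              cells$algorithm[i], cells$imputation[i]), integer(1L))
  cells[order(cells$scenario, cells$algorithm), ]
}

# deterministic 31-bit seed from a master seed and cell labels
cell_seed <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "|")
  h <- as.double(master_seed) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}

#' Run every cell of a configuration grid
#'
#' Runs [run_replications()] and [summarize_replications()] for each row of
#' the grid. When \code{out_file} is given, one result row is appended per
#' completed cell and, on re-run, cells already present in the file are
#' skipped, making long experiments resumable. Failures in a cell are
#' recorded (as a warning plus NA results) and the run continues.
#'
#' @param grid data frame from [build_grid()].
#' @param gittins optional \code{"gittins_table"} covering the largest
#'   GI/RGI trial in the grid; computed and cached automatically if needed.
#' @param out_file optional CSV checkpoint path.
#' @param verbose print one line per cell.
#' @return data frame with the grid columns plus \code{mean_pstar},
#'   \code{se_pstar}, \code{ons}, \code{ons_se}, \code{ens}, \code{ens_se},
#'   \code{bias0}, \code{bias1}.
#' @export
run_experiment <- function(grid, gittins = NULL, out_file = NULL,
                           verbose = FALSE) {
  key <- function(g) paste(g$scenario, g$pm0, g$pm1, g$algorithm,
                           g$imputation, g$R, g$seed, sep = "|")
  done <- character(0)
  prev <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    prev <- utils::read.csv(out_file, stringsAsFactors = FALSE)
    done <- key(prev)
  }
  if (any(grid$algorithm %in% c("GI", "RGI")) && is.null(gittins)) {
    nmax <- max(grid$n[grid$algorithm %in% c("GI", "RGI")])
    gittins <- cached_gittins_table(0.99, nmax + 4L)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (key(g) %in% done) next
    res <- tryCatch({
      cfg <- trial_config(algorithm = g$algorithm, p0 = g$p0, p1 = g$p1,
                          pm0 = g$pm0, pm1 = g$pm1, n = g$n,
                          imputation = g$imputation,
                          impute_initial = g$impute_initial,
                          impute_after_first = g$impute_after_first,
                          seed = g$seed)
      s <- summarize_replications(
        run_replications(cfg, R = g$R, gittins = gittins))
      data.frame(mean_pstar = s$mean_pstar, se_pstar = s$se_pstar,
                 ons = s$ons, ons_se = s$ons_se,
                 ens = s$ens, ens_se = s$ens_se,
                 bias0 = s$bias$bias[1L], bias1 = s$bias$bias[2L])
    }, error = function(e) {
      warning(sprintf("cell %s failed: %s", key(g), conditionMessage(e)),
              call. = FALSE)
      data.frame(mean_pstar = NA_real_, se_pstar = NA_real_,
                 ons = NA_real_, ons_se = NA_real_,
                 ens = NA_real_, ens_se = NA_real_,
                 bias0 = NA_real_, bias1 = NA_real_)
    })
    row <- cbind(g, res, row.names = NULL)
    rows[[i]] <- row
    if (!is.null(out_file)) {
      new_file <- !file.exists(out_file)
      utils::write.table(row, out_file, sep = ",", row.names = FALSE,
                         col.names = new_file, append = !new_file)
    }
    if (verbose)
      message(sprintf("%s %s pm=(%.1f,%.1f) %s: E[p*] = %.4f",
                      g$scenario, g$algorithm, g$pm0, g$pm1, g$imputation,
                      res$mean_pstar))
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(prev)) out <- if (is.null(out)) prev else rbind(prev, out)
  if (is.null(out)) return(invisible(NULL))
  out[order(out$scenario, out$algorithm, out$pm0, out$pm1), ]
}
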