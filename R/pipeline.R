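# End-to-end pipeline: seeded ensembles -> per-frame descriptor tables ->
# normality screen -> Welch matrices -> cluster-size scaling report.
# CSV outputs follow the per-combination naming "{size}M_{space}_{model}.csv".

#' Pipeline run configuration
#'
#' @param models Named list of [force_field()] objects
#'   (default [water_models()]).
#' @param cluster_sizes Cluster sizes to generate (default 1, 3, 5, 7, 9,
#'   11).
#' @param n_frames Frames per (model, size) ensemble.
#' @param seed Master integer seed; per-ensemble seeds are derived from it
#'   deterministically.
#' @param jitter_sigma,oo_distance_range Passed to [ensemble_spec()].
#' @param weight_mode Density weighting mode, see [make_monomer_density()].
#' @param quad A [quadrature_spec()].
#' @param r_cut Sevick O-O cutoff, angstrom.
#' @param out_dir Output directory for CSV artifacts, or `NULL` to skip
#'   writing.
#' @param holm Apply Holm correction to each Welch matrix (off by default:
#'   the protocol applies per-pair 0.05 thresholds).
#' @return An object of class `run_config`.
#' @export
run_config <- function(models = water_models(),
                       cluster_sizes = c(1, 3, 5, 7, 9, 11),
                       n_frames = 30L, seed = 1L, jitter_sigma = 0.01,
                       oo_distance_range = c(2.6, 3.2),
                       weight_mode = c("electron_count", "charge_perturbed"),
                       quad = quadrature_spec(), r_cut = 3.5,
                       out_dir = NULL, holm = FALSE) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(length(cluster_sizes) >= 1, length(models) >= 1,
            !is.null(names(models)))
  structure(list(models = models,
                 cluster_sizes = sort(unique(as.integer(cluster_sizes))),
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 jitter_sigma = jitter_sigma,
                 oo_distance_range = oo_distance_range,
                 weight_mode = weight_mode, quad = quad, r_cut = r_cut,
                 out_dir = out_dir, holm = holm),
            class = "run_config")
}

# Deterministic sub-seed per (model index, size); kept well below 2^31.
.derive_seed <- function(seed, model_idx, size) {
  (seed + 7919L * model_idx + 104729L * size) %% 2147483647L
}

#' Run the full descriptor pipeline
#'
#' For every (model, cluster size): generates a seeded jittered ensemble,
#' computes per-frame descriptor sets, then runs the normality screen per
#' (model, size, space, measure) cell and Welch's t-test on every model
#' pair per (size, space, measure). Deterministic for a fixed
#' `config$seed`. When `config$out_dir` is set, writes one CSV per
#' (size, space, model) named `{size}M_{space}_{model}.csv` (wide
#' per-frame tables), plus `normality_screen.csv`, `welch_matrix.csv` and
#' `scaling_series.csv`.
#'
#' @param config A [run_config()].
#' @return A list with `table` (long descriptor table), `normality`,
#'   `welch`, and `scaling` (`NULL` when only one size is configured).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tabs <- list()
  for (mi in seq_along(config$models)) {
    ff <- config$models[[mi]]
    for (size in config$cluster_sizes) {
      spec <- ensemble_spec(size, n_frames = config$n_frames,
                            jitter_sigma = config$jitter_sigma,
                            oo_distance_range = config$oo_distance_range,
                            seed = .derive_seed(config$seed, mi, size))
      tabs[[length(tabs) + 1L]] <-
        make_descriptor_samples(ff, spec, weight_mode = config$weight_mode,
                                quad = config$quad)
    }
  }
  table <- do.call(rbind, tabs)
  normality <- normality_table(table)
  welch <- welch_matrix(table, holm = config$holm)
  scaling <- if (length(config$cluster_sizes) >= 2) scaling_report(table)
             else NULL
  if (!is.null(config$out_dir)) {
    .write_pipeline_csvs(table, normality, welch, scaling, config$out_dir)
  }
  list(table = table, normality = normality, welch = welch,
       scaling = scaling)
}

#' Normality screen over a descriptor table
#'
#' Applies [normality_screen()] to every (model, size, space, measure)
#' cell of a long descriptor table.
#'
#' @param table Long descriptor table as returned by
#'   [make_descriptor_samples()] / [run_pipeline()]. Cells whose sample is
#'   constant (e.g. zero jitter) are reported with `NA` statistics and
#'   verdict `"degenerate"`.
#' @return A `data.frame` with one row per cell.
#' @export
normality_table <- function(table) {
  keys <- unique(table[c("model", "n_molecules", "space", "measure")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    v <- table$value[table$model == k$model &
                     table$n_molecules == k$n_molecules &
                     table$space == k$space & table$measure == k$measure]
    res <- tryCatch(normality_screen(v), error = function(e) {
      list(W = NA_real_, p_value = NA_real_, r_squared = NA_real_,
           verdict = "degenerate")
    })
    cbind(k, data.frame(n = length(v), W = res$W, p_value = res$p_value,
                        r_squared = res$r_squared, verdict = res$verdict))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch t-test matrix over a descriptor table
#'
#' Runs [welch_t()] for every model pair within every (size, space,
#' measure) cell.
#'
#' @inheritParams normality_table
#' @param holm Holm-adjust p-values within each (size, space) block before
#'   flagging significance (off by default).
#' @return A `data.frame` with columns `model_a`, `model_b`,
#'   `n_molecules`, `space`, `measure`, `t`, `df`, `p_value`,
#'   `significant`. Cells with degenerate samples (both variances zero,
#'   which the surrogate's momentum leg produces by construction, since
#'   positional jitter never reaches the displacement-independent momentum
#'   density) carry `NA` statistics.
#' @export
welch_matrix <- function(table, holm = FALSE) {
  models <- unique(table$model)
  if (length(models) < 2) stop("need at least two models", call. = FALSE)
  pairs <- utils::combn(models, 2)
  keys <- unique(table[c("n_molecules", "space", "measure")])
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      pick <- function(m) {
        table$value[table$model == m & table$n_molecules == k$n_molecules &
                    table$space == k$space & table$measure == k$measure]
      }
      res <- tryCatch(welch_t(pick(pairs[1, j]), pick(pairs[2, j])),
                      error = function(e) {
                        # degenerate cells (e.g. the ensemble-invariant
                        # momentum leg of the surrogate) yield NA, not an
                        # abort
                        list(t = NA_real_, df = NA_real_,
                             p_value = NA_real_, significant = NA)
                      })
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(model_a = pairs[1, j], model_b = pairs[2, j]),
              k, data.frame(t = res$t, df = res$df, p_value = res$p_value,
                            significant = res$significant))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (holm) {
    for (blk in split(seq_len(nrow(out)),
                      paste(out$n_molecules, out$space))) {
      adj <- stats::p.adjust(out$p_value[blk], method = "holm")
      out$significant[blk] <- adj < 0.05
    }
  }
  out
}

#' Cluster-size scaling report
#'
#' Per (measure, space, model): descriptor mean versus cluster size, the
#' normalized per-size model shares (stacked-bar data: each model's mean
#' divided by the sum of all model means at that size), and a strict
#' monotonicity flag for the mean series. Missing (model, size) cells are
#' kept as explicit `NA` gaps, never interpolated.
#'
#' @inheritParams normality_table
#' @return A list with `series`, `shares` and `monotonicity` data frames.
#' @export
scaling_report <- function(table) {
  sizes <- sort(unique(table$n_molecules))
  if (length(sizes) < 2) {
    stop("scaling_report() requires a table covering at least two sizes",
         call. = FALSE)
  }
  agg <- stats::aggregate(value ~ model + n_molecules + space + measure,
                          data = table, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean"
  grid <- expand.grid(model = unique(table$model), n_molecules = sizes,
                      space = unique(table$space),
                      measure = unique(table$measure),
                      stringsAsFactors = FALSE)
  series <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  series <- series[order(series$measure, series$space, series$model,
                         series$n_molecules), ]
  rownames(series) <- NULL
  # normalized model shares per (size, space, measure)
  shares <- series
  for (blk in split(seq_len(nrow(shares)),
                    paste(shares$n_molecules, shares$space,
                          shares$measure))) {
    tot <- sum(shares$mean[blk])
    shares$mean[blk] <- shares$mean[blk] / tot
  }
  names(shares)[names(shares) == "mean"] <- "share"
  mono_rows <- lapply(split(series,
                            paste(series$model, series$space,
                                  series$measure)), function(s) {
    s <- s[order(s$n_molecules), ]
    data.frame(model = s$model[1], space = s$space[1],
               measure = s$measure[1],
               increasing = !anyNA(s$mean) && all(diff(s$mean) > 0),
               decreasing = !anyNA(s$mean) && all(diff(s$mean) < 0))
  })
  monotonicity <- do.call(rbind, mono_rows)
  rownames(monotonicity) <- NULL
  list(series = series, shares = shares, monotonicity = monotonicity)
}

# Write the appendix-style per-combination CSVs and the stats artifacts.
.write_pipeline_csvs <- function(table, normality, welch, scaling,
                                 out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  combos <- unique(table[c("n_molecules", "space", "model")])
  for (i in seq_len(nrow(combos))) {
    k <- combos[i, ]
    sub <- table[table$n_molecules == k$n_molecules &
                 table$space == k$space & table$model == k$model, ]
    wide <- stats::reshape(sub[c("frame", "measure", "value")],
                           idvar = "frame", timevar = "measure",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    fn <- sprintf("%dM_%s_%s.csv", k$n_molecules,
                  if (k$space == "r") "position" else "momentum", k$model)
    utils::write.csv(wide, file.path(out_dir, fn), row.names = FALSE)
  }
  utils::write.csv(normality, file.path(out_dir, "normality_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(welch, file.path(out_dir, "welch_matrix.csv"),
                   row.names = FALSE)
  if (!is.null(scaling)) {
    utils::write.csv(scaling$series, file.path(out_dir,
                                               "scaling_series.csv"),
                     row.names = FALSE)
  }
  invisible(NULL)
}
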