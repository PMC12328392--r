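#' Define an HPLC gradient program
#'
#' Nodes of the binary mobile-phase gradient as (time, %A, %B) triples, with
#' holds written as explicit nodes, plus the re-equilibration time appended
#' after the last node.
#'
#' @param segments Tibble/data frame with columns `time_min`, `percent_a`,
#'   `percent_b`; times strictly increasing from 0, percentages summing
#'   to 100 at every node.
#' @param re_equilibration_min Re-equilibration time after the last node.
#' @param flow_mL_min,column,temperature_c Optional run metadata.
#' @return An object of class `gradient_program`.
#' @export
gradient_program <- function(segments, re_equilibration_min = 0,
                             flow_mL_min = NA_real_, column = NA_character_,
                             temperature_c = NA_real_) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("time_min", "percent_a", "percent_b") %in% names(segments)))
  if (segments$time_min[1] != 0) {
    stop("The gradient must start at time 0.", call. = FALSE)
  }
  if (any(diff(segments$time_min) <= 0)) {
    stop("Gradient node times must be strictly increasing.", call. = FALSE)
  }
  if (any(abs(segments$percent_a + segments$percent_b - 100) > 1e-9)) {
    stop("percent_a + percent_b must equal 100 at every node.", call. = FALSE)
  }
  if (re_equilibration_min < 0) {
    stop("`re_equilibration_min` must be >= 0.", call. = FALSE)
  }
  structure(
    list(
      segments = segments,
      re_equilibration_min = re_equilibration_min,
      flow_mL_min = flow_mL_min,
      column = column,
      temperature_c = temperature_c
    ),
    class = "gradient_program"
  )
}

#' Reference gradient program of the fingerprinting method
#'
#' The acidified water/acetonitrile program used for the fingerprints:
#' 100/0 held to 5 min, linear to 50/50 at 55 min, to 0/100 at 90 min, back
#' to 100/0 at 95 min, then 15 min re-equilibration (110 min total) at
#' 0.75 mL/min on a C18 column at 30 degC.
#'
#' @return A `gradient_program`.
#' @export
reference_gradient <- function() {
  gradient_program(
    tibble::tibble(
      time_min = c(0, 5, 55, 90, 95),
      percent_a = c(100, 100, 50, 0, 100),
      percent_b = c(0, 0, 50, 100, 0)
    ),
    re_equilibration_min = 15,
    flow_mL_min = 0.75,
    column = "C18 250 x 4 mm, 5 um",
    temperature_c = 30
  )
}

#' Total runtime of a gradient program
#'
#' Last node time plus re-equilibration.
#'
#' @param g A `gradient_program`.
#' @return Total runtime in minutes.
#' @export
total_runtime <- function(g) {
  stopifnot(inherits(g, "gradient_program"))
  max(g$segments$time_min) + g$re_equilibration_min
}

#' Mobile-phase composition at a given time
#'
#' Piecewise-linear interpolation between gradient nodes.
#'
#' @param g A `gradient_program`.
#' @param t_min Time(s) in minutes, within `[0, last node]`.
#' @return A tibble with columns `time_min`, `percent_a`, `percent_b`.
#' @export
composition_at <- function(g, t_min) {
  stopifnot(inherits(g, "gradient_program"))
  tmax <- max(g$segments$time_min)
  if (any(t_min < 0 | t_min > tmax)) {
    stop(sprintf("Time(s) outside the gradient range [0, %g] min.", tmax),
      call. = FALSE
    )
  }
  pa <- stats::approx(g$segments$time_min, g$segments$percent_a, xout = t_min)$y
  tibble::tibble(time_min = t_min, percent_a = pa, percent_b = 100 - pa)
}

#' @export
print.gradient_program <- function(x, ...) {
  cat(sprintf(
    "<gradient_program> %d nodes, %g min + %g min re-equilibration = %g min total\n",
    nrow(x$segments), max(x$segments$time_min), x$re_equilibration_min,
    total_runtime(x)
  ))
  invisible(x)
}

default_pipeline_config <- function() {
  list(
    simulate = list(seed = 1L),
    preprocess = list(
      window = c(13.2, 64.5), threshold = 0.93, consolidate = "mean",
      half_window_min = 2, iterations = 8L, smooth_window_min = 0.2
    ),
    cluster = list(sqrt_dist = TRUE, k = 2L, hopkins_seed = 1L),
    model = list(
      method = "pls", n_components = 2L, n_orthogonal = 1L,
      scale_mode = "center", cv = TRUE
    ),
    markers = list(rel_threshold = 0.1, min_width_min = 0.1, tolerance_min = 0.5),
    wavelengths_nm = c(280L, 330L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full fingerprint analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> cluster -> index -> model ->
#' markers for each analysis wavelength (280 and 330 nm by default; 254 nm is
#' recorded metadata only) and returns a machine-readable report. The
#' configuration may be a YAML/JSON file path or a nested list; any field
#' omitted falls back to the documented default. In simulation mode the
#' `simulate` section holds [sim_config()] fields; external data can instead
#' be supplied under `data:` (`dir`, `panel`, `standards`) in the CSV/JSON
#' dialect of [write_chromatograms()].
#'
#' @param config Path to a YAML/JSON config file, or a nested list.
#' @param out_dir Optional directory for the report JSON and intermediate
#'   CSVs.
#' @param verbose Log stage progress to stderr.
#' @return An object of class `run_report`: per-wavelength cluster
#'   validation, model metrics, marker intervals and standard matches, the
#'   RACI summary, the echoed config and seed.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  say <- function(...) if (verbose) message(sprintf(...))

  stage <- "simulate"
  report <- tryCatch(
    {
      if (!is.null(cfg$data)) {
        stage <- "load"
        say("[load] reading chromatograms from %s", cfg$data$dir)
        chroms <- read_chromatograms(cfg$data$dir)
        ds <- list(
          chromatograms = chroms[!chroms$blank, , drop = FALSE],
          blanks = chroms[chroms$blank, , drop = FALSE],
          assay_panel = read_assay_panel(cfg$data$panel),
          standards = if (!is.null(cfg$data$standards)) {
            read_standards(cfg$data$standards)
          } else {
            NULL
          },
          config = NULL
        )
        seed <- NA_integer_
      } else {
        sim_args <- cfg$simulate
        sc <- do.call(sim_config, sim_args)
        seed <- sc$seed
        say("[simulate] seed %d: %d x %d extracts x %d injections",
          seed, sc$n_species, sc$n_extracts_per_species,
          sc$n_injection_replicates
        )
        ds <- simulate_dataset(sc)
      }

      stage <- "index"
      # a panel with no antioxidant signal at all (every assay column
      # constant) cannot be standardised; the regression stage is skipped and
      # the marker reports stay empty
      panel_cols <- ds$assay_panel[, intersect(
        c("tp_mg_gae_g", "dpph_mg_te_g", "abts_mg_te_g", "frap_mg_te_g"),
        names(ds$assay_panel)
      )]
      flat_panel <- all(vapply(panel_cols, stats::sd, numeric(1)) == 0)
      idx <- NULL
      if (!flat_panel) {
        idx <- antioxidant_index(ds$assay_panel)
        say("[index] RACI-PC1 agreement R^2 = %.4f", idx$r_squared_mean_vs_pc1)
      } else {
        say("[index] assay panel carries no signal; skipping index and models")
      }

      per_wl <- list()
      for (wl in cfg$wavelengths_nm) {
        stage <- sprintf("preprocess@%dnm", wl)
        say("[%s]", stage)
        fm <- preprocess_dataset(
          ds, wl,
          window = cfg$preprocess$window,
          threshold = cfg$preprocess$threshold,
          consolidate = cfg$preprocess$consolidate,
          half_window_min = cfg$preprocess$half_window_min,
          iterations = cfg$preprocess$iterations,
          smooth_window_min = cfg$preprocess$smooth_window_min
        )

        stage <- sprintf("cluster@%dnm", wl)
        cv_clu <- validate_clustering(
          fm,
          sqrt_dist = cfg$cluster$sqrt_dist, k = cfg$cluster$k,
          hopkins_seed = cfg$cluster$hopkins_seed
        )
        say("[%s] CCC = %.3f, Hopkins = %.3f", stage, cv_clu$ccc, cv_clu$hopkins)

        if (flat_panel) {
          per_wl[[as.character(wl)]] <- list(
            wavelength_nm = wl,
            ccc = cv_clu$ccc,
            hopkins = cv_clu$hopkins,
            clusters = cv_clu$clusters,
            metrics = NULL,
            markers = find_marker_intervals(
              fm$time_min, rep(0, length(fm$time_min)), wavelength_nm = wl
            )
          )
          next
        }

        stage <- sprintf("model@%dnm", wl)
        y <- idx$samples$raci_mean[match(fm$sample_ids, idx$samples$sample_id)]
        if (anyNA(y)) {
          stop("Assay panel and fingerprint samples do not match.", call. = FALSE)
        }
        model <- if (cfg$model$method == "opls") {
          fit_opls(fm, y, cfg$model$n_orthogonal, cfg$model$scale_mode)
        } else {
          fit_pls(fm, y, cfg$model$n_components, cfg$model$scale_mode)
        }
        cv <- if (isTRUE(cfg$model$cv)) {
          loo_cv(fm, y,
            method = cfg$model$method,
            n_components = cfg$model$n_components,
            n_orthogonal = cfg$model$n_orthogonal,
            scale_mode = cfg$model$scale_mode
          )
        } else {
          NULL
        }
        metrics <- fit_metrics(model, fm, y, cv)
        say("[%s] R2Y = %.3f, RPD(cal) = %.2f", stage, metrics$r2y, metrics$rpd_cal)

        stage <- sprintf("markers@%dnm", wl)
        rep_ <- find_marker_intervals(
          model,
          rel_threshold = cfg$markers$rel_threshold,
          min_width_min = cfg$markers$min_width_min
        )
        if (!is.null(ds$standards)) {
          rep_ <- match_standards(rep_, ds$standards, cfg$markers$tolerance_min)
        }

        per_wl[[as.character(wl)]] <- list(
          wavelength_nm = wl,
          ccc = cv_clu$ccc,
          hopkins = cv_clu$hopkins,
          clusters = cv_clu$clusters,
          metrics = metrics,
          markers = rep_
        )
      }

      structure(
        list(
          per_wavelength = per_wl,
          raci = if (!is.null(idx)) idx$samples else NULL,
          pc1_loadings = if (!is.null(idx)) idx$pc1_loadings else NULL,
          r_squared_mean_vs_pc1 = if (!is.null(idx)) {
            idx$r_squared_mean_vs_pc1
          } else {
            NA_real_
          },
          config = cfg,
          seed = seed,
          version = as.character(utils::packageVersion("fingerchem"))
        ),
        class = "run_report"
      )
    },
    error = function(e) {
      stop(sprintf("Pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
        call. = FALSE
      )
    }
  )

  if (!is.null(out_dir)) {
    write_run_report(report, out_dir)
  }
  report
}

write_run_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(report$raci)) {
    readr::write_csv(report$raci, file.path(out_dir, "raci.csv"))
  }
  json <- list(
    seed = report$seed,
    version = report$version,
    r_squared_mean_vs_pc1 = report$r_squared_mean_vs_pc1,
    pc1_loadings = as.list(report$pc1_loadings),
    per_wavelength = lapply(report$per_wavelength, function(w) {
      list(
        wavelength_nm = w$wavelength_nm,
        ccc = w$ccc,
        hopkins = w$hopkins,
        clusters = w$clusters,
        metrics = if (!is.null(w$metrics)) as.list(w$metrics[1, ]) else NULL,
        marker_intervals = w$markers$intervals,
        standard_matches = w$markers$matches
      )
    })
  )
  jsonlite::write_json(
    json, file.path(out_dir, "run_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf(
    "  RACI vs PC1 index: R^2 = %.3g; loadings %s\n",
    x$r_squared_mean_vs_pc1,
    paste(sprintf("%.3g", x$pc1_loadings), collapse = "/")
  ))
  for (w in x$per_wavelength) {
    if (is.null(w$metrics)) {
      cat(sprintf(
        "  %d nm: CCC %.3g, Hopkins %.3g, no regression stage, %d marker interval(s)\n",
        w$wavelength_nm, w$ccc, w$hopkins, nrow(w$markers$intervals)
      ))
    } else {
      cat(sprintf(
        "  %d nm: CCC %.3g, Hopkins %.3g, R2Y %.3g, RPD(cal) %.3g, %d marker interval(s)\n",
        w$wavelength_nm, w$ccc, w$hopkins, w$metrics$r2y, w$metrics$rpd_cal,
        nrow(w$markers$intervals)
      ))
    }
  }
  invisible(x)
}
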