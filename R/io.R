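#' Fishery panel container
#'
#' The observed data rectangle: per-taxon annual catch (grams), a single
#' shared effort series (fisher counts, possibly missing), and an annual
#' temperature series, all over one contiguous year range.
#'
#' @param catch numeric matrix `[taxon, year]` of annual catch in grams
#'   (zeros allowed; negatives rejected).
#' @param effort data.frame with columns `year`, `n_fishers` (NA = missing)
#'   and optionally `missing`.
#' @param temperature data.frame with columns `year`, `temp_c`.
#' @param schemes optional named list of [period_scheme()] per taxon.
#' @return Object of class `fishery_panel`.
#' @export
fishery_panel <- function(catch, effort, temperature, schemes = NULL) {
  catch <- as.matrix(catch)
  if (is.null(rownames(catch))) stop("catch matrix must have taxon rownames")
  years <- as.integer(colnames(catch))
  if (anyNA(years)) stop("catch matrix must have year colnames")
  if (any(diff(years) != 1L)) stop("years must be contiguous")
  if (any(catch < 0, na.rm = TRUE)) stop("negative catch values")
  if (anyNA(catch)) stop("catch matrix contains NA")
  effort <- as.data.frame(effort)
  if (!all(c("year", "n_fishers") %in% names(effort))) {
    stop("effort needs columns year, n_fishers")
  }
  effort <- effort[match(years, effort$year), , drop = FALSE]
  if (anyNA(effort$year)) stop("effort series does not cover all years")
  effort$missing <- is.na(effort$n_fishers)
  obs <- effort$n_fishers[!effort$missing]
  if (any(obs != round(obs)) || any(obs < 1)) {
    stop("observed effort must be integer counts >= 1")
  }
  temperature <- as.data.frame(temperature)
  temperature <- temperature[match(years, temperature$year), , drop = FALSE]
  if (anyNA(temperature$temp_c)) {
    stop("temperature series must cover all years with no missing values")
  }
  structure(list(catch = catch, effort = effort, temperature = temperature,
                 taxa = rownames(catch), years = years, schemes = schemes),
            class = "fishery_panel")
}

#' @export
print.fishery_panel <- function(x, ...) {
  cat("Fishery panel:", length(x$taxa), "taxa,", length(x$years), "years (",
      min(x$years), "-", max(x$years), ")\n")
  cat("  missing effort years:",
      if (any(x$effort$missing)) {
        paste(x$effort$year[x$effort$missing], collapse = ", ")
      } else "none", "\n")
  invisible(x)
}

#' Write a panel as the CSV trio
#'
#' Writes `catch.csv` (taxon, year, catch_g), `effort.csv` (year,
#' n_fishers with blanks for missing years), `temperature.csv` (year,
#' temp_c) and, when schemes are attached, `schemes.csv` (taxon_id, period,
#' first_year, last_year).
#'
#' @param panel a [fishery_panel()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "fishery_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catch_long <- data.frame(
    taxon = rep(panel$taxa, times = length(panel$years)),
    year = rep(panel$years, each = length(panel$taxa)),
    catch_g = as.vector(panel$catch))
  paths <- c(catch = file.path(dir, "catch.csv"),
             effort = file.path(dir, "effort.csv"),
             temperature = file.path(dir, "temperature.csv"))
  utils::write.csv(catch_long, paths["catch"], row.names = FALSE)
  utils::write.csv(panel$effort[, c("year", "n_fishers")], paths["effort"],
                   row.names = FALSE, na = "")
  utils::write.csv(panel$temperature[, c("year", "temp_c")],
                   paths["temperature"], row.names = FALSE)
  if (!is.null(panel$schemes)) {
    sc <- do.call(rbind, lapply(panel$schemes, function(s) {
      cbind(taxon_id = s$taxon_id, s$boundaries)
    }))
    paths <- c(paths, schemes = file.path(dir, "schemes.csv"))
    utils::write.csv(sc, paths["schemes"], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a panel from the CSV trio
#'
#' Inverse of [write_panel()]. Validation errors name the offending rows.
#'
#' @param dir directory holding `catch.csv`, `effort.csv`,
#'   `temperature.csv` and optionally `schemes.csv`.
#' @param quiet suppress the missing-effort report.
#' @return A [fishery_panel()].
#' @export
read_panel <- function(dir, quiet = FALSE) {
  need <- file.path(dir, c("catch.csv", "effort.csv", "temperature.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
  catch_long <- utils::read.csv(need[1L])
  bad <- which(catch_long$catch_g < 0)
  if (length(bad)) {
    stop("negative catch in catch.csv at row(s): ", paste(bad, collapse = ", "))
  }
  effort <- utils::read.csv(need[2L])
  nonint <- which(!is.na(effort$n_fishers) &
                    effort$n_fishers != round(effort$n_fishers))
  if (length(nonint)) {
    stop("non-integer effort in effort.csv at row(s): ",
         paste(nonint, collapse = ", "))
  }
  temperature <- utils::read.csv(need[3L])
  taxa <- unique(catch_long$taxon)
  years <- sort(unique(catch_long$year))
  if (any(diff(years) != 1L)) {
    stop("catch.csv has gaps in the year range: ",
         paste(setdiff(seq(min(years), max(years)), years), collapse = ", "))
  }
  catch <- matrix(NA_real_, length(taxa), length(years),
                  dimnames = list(taxa, years))
  catch[cbind(match(catch_long$taxon, taxa), match(catch_long$year, years))] <-
    catch_long$catch_g
  schemes <- NULL
  scheme_path <- file.path(dir, "schemes.csv")
  if (file.exists(scheme_path)) {
    schemes <- read_schemes(scheme_path)
    unknown <- setdiff(names(schemes), taxa)
    if (length(unknown)) {
      stop("schemes.csv names taxa absent from catch.csv: ",
           paste(unknown, collapse = ", "))
    }
  }
  panel <- fishery_panel(catch, effort, temperature, schemes = schemes)
  if (!quiet && any(panel$effort$missing)) {
    message(sum(panel$effort$missing), " missing effort year(s): ",
            paste(panel$effort$year[panel$effort$missing], collapse = ", "))
  }
  panel
}

#' Read period schemes from CSV
#'
#' @param path CSV with columns taxon_id, period, first_year, last_year.
#' @return Named list of [period_scheme()].
#' @export
read_schemes <- function(path) {
  df <- utils::read.csv(path)
  req <- c("taxon_id", "period", "first_year", "last_year")
  if (!all(req %in% names(df))) {
    stop("schemes file must have columns: ", paste(req, collapse = ", "))
  }
  out <- lapply(split(df, df$taxon_id), function(d) {
    period_scheme(d$taxon_id[1L], d[, c("period", "first_year", "last_year")])
  })
  out[unique(df$taxon_id)]
}

#' Read a temperature series from CSV
#'
#' @param path CSV with columns year, temp_c.
#' @return data.frame with columns `year`, `temp_c`.
#' @export
read_temperature <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year", "temp_c") %in% names(df))) {
    stop("temperature file must have columns year, temp_c")
  }
  df[order(df$year), c("year", "temp_c")]
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> preprocess -> fit -> summarise -> traits, writing
#' every table plus a manifest (seed, file hashes, R-hat range) to
#' `out_dir`. Stages log wall time; a failing stage halts with a
#' stage-labelled error but earlier outputs are preserved.
#'
#' @param config list with elements:
#'   * `data`: either a directory of panel CSVs or a `sim_config`,
#'   * `sampler`: arguments forwarded to [fit_ssm()] (n_chains, n_iter, ...),
#'   * `traits`: optional path to a trait CSV (default: packaged synthetic
#'     fixture),
#'   * `seed`: integer master seed.
#' @param out_dir output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  panel <- stage("data", {
    if (inherits(config$data, "sim_config")) {
      sim <- simulate_community(config$data, seed = seed)
      write_panel(sim$panel, file.path(out_dir, "input"))
      jsonlite::write_json(
        lapply(sim$truth[c("beta", "gamma", "sigma_x", "sigma_y")], unclass),
        file.path(out_dir, "input", "truth.json"),
        auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
      sim$panel
    } else {
      read_panel(config$data, quiet = TRUE)
    }
  })
  schemes <- panel$schemes %||% default_schemes(panel$taxa,
                                                min(panel$years),
                                                max(panel$years))
  prep <- stage("preprocess", prepare_data(panel, schemes))
  fit <- stage("fit", do.call(fit_ssm, c(
    list(data = prep, seed = seed), config$sampler)))
  man_rhat <- range(fit$rhat, na.rm = TRUE)
  stage("summarize", {
    gs <- derive_period_growth(fit)
    cs <- derive_community_growth(fit)
    tr <- cpue_trajectory(fit)
    utils::write.csv(gs, file.path(out_dir, "growth_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cs, file.path(out_dir, "community_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(tr, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(quantity = names(fit$rhat), rhat = unname(fit$rhat)),
      file.path(out_dir, "rhat.csv"), row.names = FALSE)
  })
  stage("traits", {
    traits <- read_trait_table(config$traits %||%
      system.file("extdata", "trait_table_synthetic.csv",
                  package = "cpuessm", mustWork = TRUE))
    gs <- derive_period_growth(fit)
    groups <- assign_groups(gs)
    traits <- traits[match(names(groups), traits$taxon), ]
    res <- do.call(rbind, lapply(
      c("max_total_length", "female_age_maturation",
        "longevity_class", "fecundity_class"),
      function(tr) {
        val <- traits[[tr]]
        if (grepl("_class$", tr)) val <- rank_transform(val)
        fit1 <- fit_trait_model(val, groups, traits$subfamily)
        data.frame(trait = tr, coef_group2 = fit1$coef, se = fit1$se,
                   p_value = fit1$p_value, ranef_var = fit1$ranef_var,
                   singular = fit1$singular)
      }))
    utils::write.csv(cbind(data.frame(taxon = traits$taxon, group = groups),
                           row.names = NULL),
                     file.path(out_dir, "groups.csv"), row.names = FALSE)
    utils::write.csv(res, file.path(out_dir, "trait_results.csv"),
                     row.names = FALSE)
  })
  outs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outs <- outs[basename(outs) != "manifest.json"]
  manifest <- list(
    seed = seed,
    sampler = fit$config[c("n_chains", "n_iter", "warmup", "thin")],
    rhat_range = man_rhat,
    converged = all(fit$rhat < 1.1, na.rm = TRUE),
    files = as.list(stats::setNames(unname(tools::md5sum(outs)),
                                    sub(paste0(out_dir, "/?"), "", outs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
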