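#' Assemble a run configuration
#'
#' A plain list validated and filled with defaults; round-trips through
#' JSON unchanged ([read_run_config()] / [write_run_config()]).
#'
#' @param outdir output directory for all stages.
#' @param synth optional list of [synth_config()] arguments; omit when
#'   supplying real establishment/attribute/geometry files.
#' @param establishments,attributes,geojson input paths (defaults point
#'   into `outdir`, where the simulate stage writes them).
#' @param dollar_tier,mrfei_denominator taxonomy/index policy overrides.
#' @param weights_scheme `"queen"` or `"distance_band"`.
#' @param hotspot_value,hotspot_years hot-spot analysis column and years
#'   (`NULL` years = first, middle and last of the panel).
#' @param outcomes model-suite outcomes.
#' @param seed root seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, synth = list(),
                       establishments = file.path(outdir, "establishments.csv"),
                       attributes = file.path(outdir, "tract_attributes.csv"),
                       geojson = file.path(outdir, "tracts.geojson"),
                       dollar_tier = "UNHEALTHY",
                       mrfei_denominator = "healthy_unhealthy",
                       weights_scheme = "queen",
                       hotspot_value = "mrfei", hotspot_years = NULL,
                       outcomes = c("mrfei", "hhi"), seed = 20260911L) {
  structure(list(outdir = outdir, synth = synth,
                 establishments = establishments, attributes = attributes,
                 geojson = geojson, dollar_tier = dollar_tier,
                 mrfei_denominator = mrfei_denominator,
                 weights_scheme = weights_scheme,
                 hotspot_value = hotspot_value,
                 hotspot_years = hotspot_years, outcomes = outcomes,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, modifyList(
    list(outdir = dirname(path)), as.list(raw)))
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

# GeoJSON with per-tract gi_z / p_value / bin properties for mapping
write_hotspots_geojson <- function(geoms, hotspots, path) {
  hs <- as.data.table(hotspots)
  m <- match(geoms$tract_id, hs$tract_id)
  features <- Map(function(id, ring, z, p, b) {
    list(type = "Feature",
         properties = list(tract_id = id, gi_z = z, p_value = p, bin = b),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(
                           seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  }, geoms$tract_id, geoms$ring, hs$gi_z[m], hs$p_value[m], hs$bin[m])
  names(features) <- NULL
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection",
                                   features = features),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate (when a synth block is configured) -> classify ->
#' indices -> hotspots -> regress, writing each stage's outputs under
#' `config$outdir` plus a manifest of stage, files, md5 hashes, row counts
#' and wall time — enough for byte-level reproducibility checks. Any stage
#' error aborts with the stage name.
#'
#' @param config a [run_config()] (or path to its JSON).
#' @return the manifest `data.table`, invisibly written to
#'   `manifest.csv` as well.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, files, rows, secs) {
    manifest[[length(manifest) + 1L]] <<- data.table(
      stage = stage, file = files,
      md5 = unname(md5sum(files)), rows = rows, seconds = round(secs, 3))
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e)
      stop("stage \"", name, "\": ", conditionMessage(e), call. = FALSE))
    list(res = res, secs = proc.time()[["elapsed"]] - t0)
  }

  if (length(config$synth)) {
    s <- stage("simulate", {
      sc <- do.call(synth_config,
                    modifyList(list(seed = config$seed), config$synth))
      simulate_registry(sc, outdir = config$outdir)
    })
    note("simulate", s$res$files,
         c(nrow(s$res$geoms), nrow(s$res$attrs),
           nrow(s$res$establishments))[c(1, 2, 3)], s$secs)
  }

  s <- stage("classify", {
    if (!file.exists(config$establishments))
      stop("establishments file not found: ", config$establishments)
    est <- fread(config$establishments,
                 colClasses = list(character = c("tract_id", "naics")))
    cls <- classify_establishments(est, dollar_tier = config$dollar_tier)
    out <- file.path(config$outdir, "establishments_classified.csv")
    fwrite(cls, out)
    list(file = out, data = cls)
  })
  note("classify", s$res$file, nrow(s$res$data), s$secs)
  classified <- s$res$data

  s <- stage("indices", {
    panel <- build_indices_panel(
      classified, mrfei_denominator = config$mrfei_denominator)
    out <- file.path(config$outdir, "indices_panel.csv")
    fwrite(panel, out)
    list(file = out, data = panel)
  })
  note("indices", s$res$file, nrow(s$res$data), s$secs)
  panel <- s$res$data

  s <- stage("hotspots", {
    geoms <- read_tracts_geojson(config$geojson)
    w <- build_weights(geoms, scheme = config$weights_scheme)
    yrs <- config$hotspot_years
    if (is.null(yrs)) {
      all_y <- sort(unique(panel$year))
      yrs <- unique(all_y[c(1L, ceiling(length(all_y) / 2), length(all_y))])
    }
    hs <- hotspot_panel(panel, w, value = config$hotspot_value, years = yrs)
    out_csv <- file.path(config$outdir, "hotspots.csv")
    fwrite(hs, out_csv)
    out_gj <- vapply(yrs, function(yr) {
      p <- file.path(config$outdir, sprintf("hotspots_%d.geojson", yr))
      write_hotspots_geojson(geoms, hs[year == yr], p)
      p
    }, character(1))
    list(files = c(out_csv, out_gj), data = hs)
  })
  note("hotspots", s$res$files,
       c(nrow(s$res$data), rep(NA_integer_, length(s$res$files) - 1L)),
       s$secs)

  s <- stage("regress", {
    if (!file.exists(config$attributes))
      stop("attributes file not found: ", config$attributes)
    attrs <- fread(config$attributes,
                   colClasses = list(character = "tract_id"))
    suite <- run_model_suite(panel, attrs, outcomes = config$outcomes)
    out <- file.path(config$outdir, "coefficients.csv")
    fwrite(suite, out)
    rep_path <- file.path(config$outdir, "regression_report.txt")
    writeLines(utils::capture.output(
      for (m in unique(suite$model_id)) {
        cat("==", m, "==\n")
        print(suite[model_id == m,
                    .(term, estimate = signif(estimate, 4),
                      se = signif(se, 4), z = round(z, 2),
                      n_obs = n_obs)])
        cat("\n")
      }), rep_path)
    list(files = c(out, rep_path), data = suite)
  })
  note("regress", s$res$files,
       c(nrow(s$res$data), NA_integer_), s$secs)

  man <- rbindlist(manifest)
  fwrite(man, file.path(config$outdir, "manifest.csv"))
  man[]
}

#' Write the bundled mini-fixture
#'
#' A 5 x 5-lattice, 3-year bundle (establishments, attributes, GeoJSON)
#' with hand-checkable counts. Two deterministic records are appended when
#' the draw does not already contain them, guaranteeing rule coverage: one
#' grocery-coded record with fewer than five employees and one 452319
#' record without "dollar" in its name.
#'
#' @param seed integer seed.
#' @param outdir optional directory to write the three files into.
#' @return list `geoms`, `attrs`, `establishments` (and `files`).
#' @export
make_fixtures <- function(seed = 42L, outdir = NULL) {
  cfg <- synth_config(n_rows = 5L, n_cols = 5L, years = 2000:2002,
                      seed = seed)
  bundle <- simulate_registry(cfg)
  est <- bundle$establishments
  cls <- classify_outlets(est$naics, est$employees, est$name)
  if (!any(est$naics == "445110" & est$employees < 5)) {
    est <- rbind(est, data.table(
      establishment_id = "EFIX0001", tract_id = "001001", year = 2000L,
      naics = "445110", name = "Fixture Corner Grocery", employees = 2L,
      sales = 150000))
  }
  if (!any(est$naics == "452319" &
           !grepl("dollar", est$name, ignore.case = TRUE))) {
    est <- rbind(est, data.table(
      establishment_id = "EFIX0002", tract_id = "001001", year = 2000L,
      naics = "452319", name = "Fixture Bargain Mart", employees = 6L,
      sales = 500000))
  }
  bundle$establishments <- est
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(outdir, c("tracts.geojson", "tract_attributes.csv",
                                 "establishments.csv"))
    write_tracts_geojson(bundle$geoms, files[1])
    fwrite(bundle$attrs, files[2])
    fwrite(bundle$establishments, files[3])
    bundle$files <- files
  }
  bundle
}
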