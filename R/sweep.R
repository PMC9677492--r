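# Parameter sweeps over the driven radical-pair model: the tabular driver
# behind the CLI script and the figure-style anisotropy maps.

SWEEPABLE <- c("J0", "D0", "nu_d", "delta_d", "magnitude", "damping_rate")

#' Configure a parameter sweep
#'
#' Defines a grid over model parameters and the observable evaluated at each
#' grid point. Axis parameters resolve to coupling laws (`J0`, `D0`), the
#' trajectory (`nu_d`, `delta_d`, `damping_rate`) or the field
#' (`magnitude`).
#'
#' @param model Registry model name (see [model_registry()]); `"two_level"`
#'   is not sweepable (no full spin system).
#' @param axes Named list; each element either a numeric vector of grid
#'   values or a list with `from`, `to`, `n` (alias `count`, safer in YAML
#'   where a bare `n` key parses as a boolean) and optional
#'   `spacing = "linear"|"log"`.
#' @param trajectory Named list of [trajectory_spec()] arguments (the swept
#'   axes override its `nu_d` / `delta_d` / `damping_rate`).
#' @param field Named list with `magnitude` (uT).
#' @param observable `"chi_axial"` (parallel/perpendicular anisotropy,
#'   default) or `"chi_sphere"` (icosphere orientation average).
#' @param orientation_frequency Icosphere subdivision for `"chi_sphere"`.
#' @param n_steps Propagation steps per driving period.
#' @param model_args Extra arguments for the model constructor.
#' @param seed Integer seed recorded in the metadata (used by Brownian
#'   trajectories).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(model = "one_nitrogen", axes = list(),
                         trajectory = list(kind = "harmonic", delta_d = 3, nu_d = 3),
                         field = list(magnitude = 50),
                         observable = c("chi_axial", "chi_sphere"),
                         orientation_frequency = 4L, n_steps = 256L,
                         model_args = list(), seed = 1L) {
  observable <- match.arg(observable)
  if (!length(axes)) stop("at least one sweep axis is required", call. = FALSE)
  bad <- setdiff(names(axes), SWEEPABLE)
  if (length(bad)) {
    stop(
      "unknown sweep parameter(s): ", paste(bad, collapse = ", "),
      "; sweepable: ", paste(SWEEPABLE, collapse = ", "),
      call. = FALSE
    )
  }
  axes <- lapply(axes, function(ax) {
    if (is.numeric(ax)) {
      return(as.numeric(ax))
    }
    stopifnot(is.list(ax))
    n_pts <- ax[["n"]] %||% ax[["count"]]
    stopifnot(length(n_pts) == 1, n_pts >= 1)
    spacing <- ax$spacing %||% "linear"
    if (spacing == "log") {
      exp(seq(log(ax$from), log(ax$to), length.out = n_pts))
    } else {
      seq(ax$from, ax$to, length.out = n_pts)
    }
  })
  structure(
    list(
      model = model, axes = axes, trajectory = trajectory, field = field,
      observable = observable,
      orientation_frequency = as.integer(orientation_frequency),
      n_steps = as.integer(n_steps), model_args = model_args,
      seed = as.integer(seed)
    ),
    class = "sweep_config"
  )
}

#' Read a sweep configuration from YAML or JSON
#'
#' @param path File path; format inferred from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return A `sweep_config`.
#' @export
read_sweep_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sweep_config, cfg)
}

# evaluate the configured observable at one grid point
eval_sweep_point <- function(point, config, model) {
  laws <- model$laws
  spec <- do.call(trajectory_spec, config$trajectory)
  magnitude <- config$field$magnitude %||% 50
  for (p in names(point)) {
    v <- point[[p]]
    switch(p,
      J0 = laws$J0 <- v,
      D0 = laws$D0 <- v,
      nu_d = spec$nu_d <- v,
      delta_d = spec$delta_d <- v,
      damping_rate = spec$damping_rate <- v,
      magnitude = magnitude <- v
    )
  }
  propagate <- if (spec$kind %in% c("static", "harmonic")) {
    function(fld) propagate_yield_floquet(model$system, fld, laws, spec,
      n_steps = config$n_steps
    )$phi_s
  } else {
    function(fld) propagate_yield_direct(model$system, fld, laws, spec,
      n_steps = config$n_steps
    )$phi_s
  }
  if (config$observable == "chi_axial") {
    ppar <- propagate(field_spec(magnitude, "parallel"))
    pperp <- propagate(field_spec(magnitude, "perpendicular"))
    tibble::tibble(
      phi_par = ppar, phi_perp = pperp,
      phi_mean = axial_mean_yield(ppar, pperp),
      chi = relative_anisotropy_axial(ppar, pperp)
    )
  } else {
    grid <- orientation_grid(config$orientation_frequency)
    ys <- orientation_yields(model$system, laws, spec, grid,
      magnitude = magnitude,
      method = if (spec$kind %in% c("static", "harmonic")) "floquet" else "direct",
      n_steps = config$n_steps
    )
    tibble::tibble(
      phi_min = min(ys$phi_s), phi_max = max(ys$phi_s),
      phi_mean = mean(ys$phi_s),
      chi = anisotropy_over_sphere(ys$phi_s)
    )
  }
}

#' Run a parameter sweep
#'
#' Evaluates the configured observable over the full axis grid and returns
#' a tidy anisotropy map. Grid points are independent; results do not
#' depend on evaluation order. Optionally persists the results as CSV and
#' the provenance metadata (package version, configuration, its hash, seed)
#' as JSON.
#'
#' @param config A [sweep_config()] (or a path accepted by
#'   [read_sweep_config()]).
#' @param csv Optional path: write the long-format results table.
#' @param json Optional path: write run metadata.
#' @return An object of class `anisotropy_map`: `results` (tibble with one
#'   row per grid point: swept parameters, yields, `chi`), `config`, and
#'   `meta`. [tidy()] returns the results tibble; [autoplot()] draws the
#'   map.
#' @export
run_sweep <- function(config, csv = NULL, json = NULL) {
  if (is.character(config)) config <- read_sweep_config(config)
  stopifnot(inherits(config, "sweep_config"))
  model <- do.call(
    model_registry,
    c(list(name = config$model), config$model_args)
  )
  if (is.null(model$system)) {
    stop("model ", config$model, " cannot be swept (no full spin system)",
      call. = FALSE
    )
  }
  grid <- do.call(tidyr::expand_grid, config$axes)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    point <- as.list(grid[i, ])
    dplyr::bind_cols(grid[i, ], eval_sweep_point(point, config, model))
  })
  results <- dplyr::bind_rows(rows)
  meta <- list(
    package = "rpdrive",
    version = as.character(utils::packageVersion("rpdrive")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_points = nrow(results),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  map <- structure(
    list(results = results, config = config, meta = meta),
    class = "anisotropy_map"
  )
  if (!is.null(csv)) {
    utils::write.csv(results, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(meta = meta, config = unclass(config)),
      json,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  map
}

#' @export
print.anisotropy_map <- function(x, ...) {
  cat(sprintf(
    "<anisotropy_map> %s over %d grid point(s); axes: %s\n",
    x$config$observable, nrow(x$results),
    paste(names(x$config$axes), collapse = " x ")
  ))
  print(x$results)
  invisible(x)
}

#' @rdname run_sweep
#' @param x An `anisotropy_map`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.anisotropy_map <- function(x, ...) x$results

#' @rdname run_sweep
#' @exportS3Method generics::glance
glance.anisotropy_map <- function(x, ...) {
  tibble::tibble(
    observable = x$config$observable,
    n_points = nrow(x$results),
    chi_min = min(x$results$chi),
    chi_max = max(x$results$chi),
    config_hash = x$meta$config_hash
  )
}
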