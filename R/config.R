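## Flat key = value run configuration, shared by all CLI subcommands.
## CLI flags override file values; the file roundtrips losslessly.

#' Default run configuration
#'
#' Named list of every tunable the command-line interface understands:
#' geometry kind and parameters, pore settings, transition parameters and
#' seed. Serializable to a flat \code{key = value} file.
#'
#' @return named list of defaults.
#' @seealso [readRunConfig()], [writeRunConfig()]
#' @export
defaultRunConfig <- function() {
    list(
        geometry = "slab",         # slab | ellipsoid | vesicle | double_vesicle
        inner_radius = 0,          # ellipsoid planar-disc radius (A)
        radius = 100,              # vesicle mid-surface radius (A)
        curvature = "down",        # vesicle curvature sign
        dv_inner_radius = 1000,    # double-vesicle inner mid-surface radius (A)
        distance = 40,             # double-vesicle edge-to-edge gap (A)
        thickness = 15,            # transition half-thickness t (A)
        steepness = 10,            # transition exponent n
        has_pore = FALSE,
        pore_radius = 5,           # pore radius rho0 (A)
        pore_x = 0, pore_y = 0,    # pore-axis intercept
        pore_steepness = 10,       # pore exponent m
        seed = 1,
        log_level = "info"
    )
}

#' Read a run configuration file
#'
#' Flat \code{key = value} lines (\code{#} comments and blank lines ignored);
#' unknown keys raise an error, values are coerced to the type of the
#' corresponding default.
#'
#' @param path path to the configuration file.
#' @param base configuration to overlay onto (default [defaultRunConfig()]).
#' @return named list (a complete run configuration).
#' @export
readRunConfig <- function(path, base = defaultRunConfig()) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    cfg <- base
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) stop("malformed config line: ", ln)
        key <- trimws(kv[1L])
        val <- trimws(kv[2L])
        if (!key %in% names(cfg)) stop("unknown config key: ", key)
        cfg[[key]] <- coerceLike(val, cfg[[key]])
    }
    cfg
}

coerceLike <- function(value, template) {
    if (is.logical(template)) {
        v <- toupper(value) %in% c("TRUE", "T", "1", "YES")
        if (!v && !(toupper(value) %in% c("FALSE", "F", "0", "NO"))) {
            stop("cannot interpret '", value, "' as logical")
        }
        v
    } else if (is.numeric(template)) {
        v <- suppressWarnings(as.numeric(value))
        if (is.na(v)) stop("cannot interpret '", value, "' as numeric")
        v
    } else {
        value
    }
}

#' Write a run configuration file
#'
#' @param config named list as returned by [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    fmt <- function(v) {
        if (is.logical(v)) {
            if (v) "TRUE" else "FALSE"
        } else if (is.numeric(v)) {
            format(v, digits = 15, scientific = FALSE)
        } else {
            as.character(v)
        }
    }
    writeLines(sprintf("%s = %s", names(config),
                       vapply(config, fmt, character(1L))), path)
    invisible(path)
}

## Materialise S4 objects from a run configuration.
paramsFromConfig <- function(cfg) {
    TransitionParams(halfThickness = cfg$thickness, steepness = cfg$steepness)
}

geometryFromConfig <- function(cfg) {
    switch(cfg$geometry,
        slab = slabGeometry(),
        ellipsoid = ellipsoidGeometry(innerRadius = cfg$inner_radius),
        vesicle = vesicleGeometry(radius = cfg$radius,
                                  curvature = cfg$curvature),
        double_vesicle = doubleVesicleGeometry(
            innerRadius = cfg$dv_inner_radius, distance = cfg$distance),
        stop("unknown geometry kind: ", cfg$geometry)
    )
}

poreFromConfig <- function(cfg) {
    if (!isTRUE(cfg$has_pore)) return(NULL)
    poreSpec(radius = cfg$pore_radius, x0 = cfg$pore_x, y0 = cfg$pore_y,
             steepness = cfg$pore_steepness)
}
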