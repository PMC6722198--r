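# Configuration and result serialisation. The run configuration is a flat
# TOML table (key = value); since no TOML reader is available in the
# supported dependency set and the schema needs no nesting, a minimal
# reader for that flat subset (comments, numbers, strings, booleans,
# one-line numeric arrays) is included here.

.config_keys <- c("D_eff", "v", "P", "B1max", "k1on", "k1off",
                  "B2max", "k2on", "k2off",
                  "F", "Dose", "ka", "ke", "V",
                  "xr", "yr", "nx", "ny")
.config_extra <- c("route", "rtol", "atol", "advection_scheme", "max_step",
                   "t_end", "output_times", "snapshot_times", "outdir")

# parse one TOML scalar / one-line array
parse_toml_value <- function(txt, key) {
  txt <- trimws(txt)
  if (grepl("^\\[", txt)) {
    inner <- sub("^\\[", "", sub("\\]$", "", txt))
    if (!grepl("\\]$", txt))
      stop("config: unterminated array for key '", key, "'")
    parts <- trimws(strsplit(inner, ",")[[1]])
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop("config: non-numeric array element for key '", key, "'")
    return(vals)
  }
  if (grepl('^"', txt)) {
    if (!grepl('"$', txt) || nchar(txt) < 2)
      stop("config: unterminated string for key '", key, "'")
    return(substr(txt, 2, nchar(txt) - 1))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val))
    stop("config: cannot parse value '", txt, "' for key '", key, "'")
  val
}

read_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln))
      stop("config: TOML tables are not supported; use flat key = value")
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop("config: cannot parse line: ", ln)
    out[[m[2]]] <- parse_toml_value(m[3], m[2])
  }
  out
}

#' Load a run configuration
#'
#' Reads a flat TOML file with keys named after the model symbols
#' (`D_eff, v, P, B1max, k1on, k1off, B2max, k2on, k2off, F, Dose, ka, ke,
#' V, xr, yr, nx, ny`) plus optional solver/run keys (`route, rtol, atol,
#' advection_scheme, max_step, t_end, output_times, snapshot_times,
#' outdir`). Missing keys fall back to the defaults of [default_params()];
#' unknown keys, wrong types and negative values are errors naming the key.
#'
#' @param path Path to the config file; `NULL` gives the all-default
#'   configuration.
#' @return A list of class `btu_config`: `drug`, `dosing`, `domain`,
#'   `opts`, `t_end`, `output_times`, `snapshot_times`, `outdir`, and
#'   `provenance` (named character, `"user"` or `"default"` per key).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("load_config: no such file: ", path)
    read_flat_toml(path)
  }
  unknown <- setdiff(names(raw), c(.config_keys, .config_extra))
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))

  def <- default_params()
  defaults <- c(unclass(def$drug),
                list(F = def$dosing$F_bio, Dose = def$dosing$Dose,
                     ka = def$dosing$ka, ke = def$dosing$ke,
                     V = def$dosing$V,
                     xr = def$domain$xr, yr = def$domain$yr,
                     nx = def$domain$nx, ny = def$domain$ny,
                     route = "oral", rtol = 1e-6, atol = 1e-12,
                     advection_scheme = "central", max_step = Inf,
                     t_end = 2e5, output_times = NULL,
                     snapshot_times = NULL, outdir = "."))
  vals <- defaults
  for (k in names(raw)) {
    v <- raw[[k]]
    want_char <- k %in% c("route", "advection_scheme", "outdir")
    if (want_char && !is.character(v))
      stop("load_config: key '", k, "' must be a string")
    if (!want_char && !is.numeric(v) && !k %in% c("output_times", "snapshot_times"))
      stop("load_config: key '", k, "' must be numeric")
    if (is.numeric(v) && length(v) == 1L && v < 0 &&
        !k %in% c("max_step"))
      stop("load_config: key '", k, "' must be non-negative, got ", v)
    vals[[k]] <- v
  }
  provenance <- stats::setNames(ifelse(names(defaults) %in% names(raw),
                                       "user", "default"), names(defaults))

  drug <- drug_params(D_eff = vals$D_eff, v = vals$v, P = vals$P,
                      k1on = vals$k1on, k1off = vals$k1off,
                      B1max = vals$B1max, k2on = vals$k2on,
                      k2off = vals$k2off, B2max = vals$B2max)
  dosing <- dosing_params(route = vals$route, F_bio = vals$F,
                          Dose = vals$Dose, ka = vals$ka, ke = vals$ke,
                          V = vals$V)
  domain <- domain2d(xr = vals$xr, yr = vals$yr, nx = vals$nx, ny = vals$ny)
  opts <- solver_options(rtol = vals$rtol, atol = vals$atol,
                         advection_scheme = vals$advection_scheme,
                         max_step = vals$max_step)
  structure(list(drug = drug, dosing = dosing, domain = domain, opts = opts,
                 t_end = vals$t_end, output_times = vals$output_times,
                 snapshot_times = vals$snapshot_times, outdir = vals$outdir,
                 provenance = provenance),
            class = "btu_config")
}

#' Write a configuration to a flat TOML file
#'
#' Inverse of [load_config()] for the model keys; round-trips losslessly.
#'
#' @param cfg A `btu_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "btu_config"))
  num <- function(x) format(x, digits = 17)
  lines <- c(
    sprintf("%s = %s", c("D_eff", "v", "P", "B1max", "k1on", "k1off",
                         "B2max", "k2on", "k2off"),
            vapply(cfg$drug[c("D_eff", "v", "P", "B1max", "k1on", "k1off",
                              "B2max", "k2on", "k2off")], num, "")),
    sprintf('route = "%s"', cfg$dosing$route),
    sprintf("F = %s", num(cfg$dosing$F_bio)),
    sprintf("Dose = %s", num(cfg$dosing$Dose)),
    sprintf("ka = %s", num(cfg$dosing$ka)),
    sprintf("ke = %s", num(cfg$dosing$ke)),
    sprintf("V = %s", num(cfg$dosing$V)),
    sprintf("xr = %s", num(cfg$domain$xr)),
    sprintf("yr = %s", num(cfg$domain$yr)),
    sprintf("nx = %d", cfg$domain$nx),
    sprintf("ny = %d", cfg$domain$ny),
    sprintf("rtol = %s", num(cfg$opts$rtol)),
    sprintf("atol = %s", num(cfg$opts$atol)),
    sprintf('advection_scheme = "%s"', cfg$opts$advection_scheme),
    sprintf("t_end = %s", num(cfg$t_end)))
  if (is.finite(cfg$opts$max_step))
    lines <- c(lines, sprintf("max_step = %s", num(cfg$opts$max_step)))
  if (!is.null(cfg$output_times))
    lines <- c(lines, sprintf("output_times = [%s]",
                              paste(num(cfg$output_times), collapse = ", ")))
  if (!is.null(cfg$snapshot_times))
    lines <- c(lines, sprintf("snapshot_times = [%s]",
                              paste(num(cfg$snapshot_times), collapse = ", ")))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulation results to disk
#'
#' Writes `timeseries.csv` (`t,C_pl,C_ECF_center,B1_center,B2_center`),
#' `snapshots.csv` (`t,i,j,x_m,y_m,C,B1,B2`; node indices 0-based,
#' coordinates in metres; only if snapshots exist) and `meta.json` (full
#' parameter set, grid, solver options, package version, dimensionless
#' groups, mass-balance residual summary).
#'
#' @param result A `btu_result`.
#' @param outdir Output directory (created if needed).
#' @return Data.frame manifest with columns `path`, `md5`.
#' @export
write_result <- function(result, outdir) {
  stopifnot(inherits(result, "btu_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  ts <- data.frame(t = result$times, C_pl = result$cpl,
                   C_ECF_center = result$center$C,
                   B1_center = result$center$B1,
                   B2_center = result$center$B2)
  p1 <- file.path(outdir, "timeseries.csv")
  utils::write.csv(ts, p1, row.names = FALSE)
  paths <- c(paths, p1)

  if (length(result$snapshots)) {
    gc_ <- grid_coords(result$dom)
    nx <- result$dom$nx; ny <- result$dom$ny
    ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
    snap <- do.call(rbind, lapply(result$snapshots, function(s)
      data.frame(t = s$t, i = ij$i, j = ij$j,
                 x_m = gc_$x[ij$i + 1L], y_m = gc_$y[ij$j + 1L],
                 C = as.numeric(s$C), B1 = as.numeric(s$B1),
                 B2 = as.numeric(s$B2))))
    p2 <- file.path(outdir, "snapshots.csv")
    utils::write.csv(snap, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }

  groups <- nondimensionalize(result$dp, result$dos, result$dom)
  meta <- list(
    package = "btu2d",
    version = as.character(utils::packageVersion("btu2d")),
    drug = unclass(result$dp),
    dosing = unclass(result$dos),
    domain = unclass(result$dom)[c("xr", "yr", "nx", "ny")],
    solver = unclass(result$opts),
    t_end = max(result$times),
    n_output_times = length(result$times),
    dimensionless = groups[c("peclet", "biot", "damkohler1", "damkohler2",
                             "t_diff", "k_ex", "t_exchange")],
    diagnostics = result$diagnostics[c("n_accept", "n_reject", "n_jac",
                                       "mass_balance_rel")])
  meta$solver$max_step <- if (is.finite(meta$solver$max_step))
    meta$solver$max_step else "Inf"
  p3 <- file.path(outdir, "meta.json")
  jsonlite::write_json(meta, p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p3)

  data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}
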