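# Shared reader for the package's delimited-text dialect: comma-separated,
# '.' decimal, UTF-8, '#' comment lines, mandatory named header. Values are
# written with 17 significant digits so read(write(x)) round-trips doubles
# exactly.

read_delimited <- function(path, required) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1) stop("empty file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  missing <- setdiff(required, header)
  if (length(missing) > 0)
    stop("missing column(s) ", paste(missing, collapse = ", "),
         " in header (line ", lineno[1], ") of ", path)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) != length(header))
  if (length(bad) > 0)
    stop("malformed row at line ", lineno[-1][bad[1]], " of ", path,
         ": expected ", length(header), " fields")
  mat <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r), numeric(length(header))))
  mat <- matrix(mat, ncol = length(header), byrow = TRUE)
  badnum <- which(apply(mat, 1, anyNA))
  if (length(badnum) > 0)
    stop("non-numeric value at line ", lineno[-1][badnum[1]], " of ", path)
  df <- as.data.frame(mat)
  names(df) <- header
  df
}

write_delimited <- function(df, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = ","), con)
  body <- apply(vapply(df, function(col) sprintf("%.17g", col),
                       character(nrow(df))), 1, paste, collapse = ",")
  writeLines(body, con)
  invisible(path)
}

#' Read / write force-extension curves
#'
#' Force-extension curves are stored as comma-separated text with the header
#' `force_pN,extension_nm`; lines starting with `#` are comments. Values are
#' serialized with 17 significant digits, so `read_fec(write_fec(x))`
#' round-trips to full double precision.
#'
#' @param path File path.
#' @param curve A [fec()] curve (or data frame with `force`, `extension`).
#' @param comment Optional comment line written at the top of the file.
#' @return `read_fec()` returns a [fec()] object; `write_fec()` returns
#'   `path` invisibly.
#' @export
read_fec <- function(path) {
  df <- read_delimited(path, c("force_pN", "extension_nm"))
  fec(df$force_pN, df$extension_nm)
}

#' @rdname read_fec
#' @export
write_fec <- function(curve, path, comment = NULL) {
  if (!all(c("force", "extension") %in% names(curve)))
    stop("'curve' needs columns 'force' and 'extension'")
  write_delimited(data.frame(force_pN = curve$force,
                             extension_nm = curve$extension),
                  path, comment)
}

#' Read / write kinetic trajectories
#'
#' Trajectories are stored as comma-separated text with columns `time_s`,
#' one `n_<label>` column per binding mode, `coverage_total` and
#' `extension_nm` (`#` comments allowed, 17 significant digits).
#'
#' @param path File path.
#' @param traj A `kinetic_trajectory` with extension filled (see
#'   [integrate_kinetics()]).
#' @param comment Optional comment line.
#' @return `read_trajectory()` returns a data frame; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  df <- read_delimited(path, c("time_s", "extension_nm"))
  names(df)[names(df) == "time_s"] <- "time"
  names(df)[names(df) == "extension_nm"] <- "extension"
  df
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path, comment = NULL) {
  if (is.null(traj$extension))
    stop("trajectory has no extension; run extension_timeseries() first")
  m <- vapply(traj$modes, `[[`, numeric(1), "m")
  df <- data.frame(time_s = traj$time)
  cn <- colnames(traj$counts)
  for (j in seq_along(cn)) df[[paste0("n_", cn[j])]] <- traj$counts[, j]
  df$coverage_total <- as.vector(traj$counts %*% m) / traj$polymer$N
  df$extension_nm <- traj$extension
  write_delimited(df, path, comment)
}

#' Read / write a model configuration
#'
#' Model configurations are YAML (JSON is valid YAML and therefore also
#' accepted) with a mandatory `polymer` block (`N`, `d0`, `Lp`, `K0`,
#' optional `kBT`), a `modes` list (each with `m`, `a` and optional `label`,
#' `eps_b`, `kb`, `kr`), and optional `kinetics`
#' (`s`, `k12`, `k21`) and `generation` (`fmin`, `fmax`, `points`,
#' `noise_sd`, `seed`) blocks. Unknown keys anywhere are rejected, and all
#' component invariants are validated on load.
#'
#' @param path File path.
#' @param config A list as returned by `read_model_config()`.
#' @return `read_model_config()` returns a list with elements `polymer`
#'   (a [polymer_spec()]), `modes` (list of [binding_mode()]), and the
#'   optional `kinetics` and `generation` blocks.
#' @export
read_model_config <- function(path) {
  # bool handlers keep YAML 1.1 from reading the key `N` as boolean FALSE
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra) > 0)
      stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  check_keys(raw, c("polymer", "modes", "kinetics", "generation"), "config")
  if (is.null(raw$polymer) || is.null(raw$modes))
    stop("config needs 'polymer' and 'modes' blocks")
  check_keys(raw$polymer, c("N", "d0", "Lp", "K0", "kBT"), "polymer")
  polymer <- do.call(polymer_spec, raw$polymer)
  modes <- lapply(seq_along(raw$modes), function(i) {
    blk <- raw$modes[[i]]
    check_keys(blk, c("label", "m", "a", "eps_b", "kb", "kr"),
               sprintf("modes[%d]", i))
    do.call(binding_mode, blk)
  })
  kin <- raw$kinetics
  if (!is.null(kin))
    check_keys(kin, c("s", "k12", "k21"), "kinetics")
  gen <- raw$generation
  if (!is.null(gen))
    check_keys(gen, c("fmin", "fmax", "points", "noise_sd", "seed"),
               "generation")
  list(polymer = polymer, modes = modes, kinetics = kin, generation = gen)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  strip <- function(x) x[!vapply(x, is.null, logical(1))]
  out <- list(
    polymer = unclass(config$polymer),
    modes = lapply(config$modes, function(md) strip(unclass(md))))
  if (!is.null(config$kinetics)) out$kinetics <- config$kinetics
  if (!is.null(config$generation)) out$generation <- config$generation
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build a kinetic scheme from a model configuration
#'
#' Combines the `modes` and optional `kinetics` blocks of a configuration
#' (see [read_model_config()]) into a [kinetic_scheme()].
#'
#' @param config A configuration list.
#' @return A [kinetic_scheme()].
#' @export
config_scheme <- function(config) {
  kin <- config$kinetics
  kinetic_scheme(config$modes, s = kin$s, k12 = kin$k12, k21 = kin$k21)
}

#' Write a fit report as JSON
#'
#' Serializes the estimates, approximate standard errors, residual sum of
#' squares and fit settings of a [fit_fec()] or [fit_kinetics()] result.
#'
#' @param fit A `polyligand_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  rep <- list(
    type = class(fit)[1],
    estimates = as.list(fit$coefficients),
    free = fit$free,
    rss = fit$rss,
    npoints = fit$npoints,
    convergence = fit$convergence,
    n_evaluations = fit$nevals)
  if (!is.null(fit$se)) rep$approx_se <- as.list(fit$se)
  if (!is.null(fit$log10_se)) rep$log10_se <- as.list(fit$log10_se)
  if (!is.null(fit$m_profile)) rep$m_profile <- fit$m_profile
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Equilibrium coverage and extension versus force
#'
#' Convenience wrapper reproducing the standard two-panel equilibrium
#' computation: for each force, the equilibrium coverage (ideal-gas, capped
#' at 100%, or Tonks-gas statistics) and the corresponding end-to-end
#' extension obtained by feeding the equilibrium counts back into the
#' force-extension model.
#'
#' @param polymer A [polymer_spec()].
#' @param mode A `binding_mode` with `eps_b`.
#' @param forces Force grid, pN.
#' @param statistics `"ideal"` or `"tonks"`.
#' @return A data frame with columns `force_pN`, `coverage`, `extension_nm`.
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' ssb <- binding_mode(m = 65, a = 5, eps_b = 0.5 * 65 * 4.11)
#' eq <- equilibrium_curve(ssdna, ssb, forces = seq(1, 25, by = 4))
#' eq
#' @export
equilibrium_curve <- function(polymer, mode, forces = seq(0.5, 30, by = 0.25),
                              statistics = c("ideal", "tonks")) {
  statistics <- match.arg(statistics)
  mode <- as_mode_list(mode)[[1]]
  cov <- vapply(forces, function(f) switch(statistics,
    ideal = equilibrium_ideal(f, polymer, mode)$total_coverage,
    tonks = equilibrium_coverage_tonks(f, polymer, mode)), numeric(1))
  ext <- vapply(seq_along(forces), function(i)
    total_extension(forces[i], polymer, mode, coverage = cov[i]),
    numeric(1))
  data.frame(force_pN = forces, coverage = cov, extension_nm = ext)
}
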