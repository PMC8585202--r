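# ---- run configuration ----------------------------------------------------

#' Assemble a run configuration
#'
#' Bundles everything one screening run needs; [read_params()] and
#' [write_params()] serialise it to the plain-text `key = value` parameter
#' dialect.
#'
#' @param lipid a [lipid_spec()] or preset name.
#' @param agent an [agent_spec()] or preset name.
#' @param geometry a [membrane_geometry()].
#' @param env an [environment_params()].
#' @param sim a [simulation_params()].
#' @param n_replicates number of replicate membranes (>= 1).
#' @param output_dir directory for CLI outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(lipid, agent, geometry = membrane_geometry(),
                       env = environment_params(),
                       sim = simulation_params(), n_replicates = 1,
                       output_dir = ".") {
  if (is.character(lipid)) lipid <- preset_lipid(lipid)
  if (is.character(agent)) agent <- preset_agent(agent)
  stopifnot(inherits(lipid, "lipid_spec"), inherits(agent, "agent_spec"),
            inherits(geometry, "membrane_geometry"),
            inherits(env, "environment_params"),
            inherits(sim, "simulation_params"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(lipid = lipid, agent = agent, geometry = geometry,
                 env = env, sim = sim,
                 n_replicates = as.integer(n_replicates),
                 output_dir = output_dir),
            class = "run_config")
}

.num_keys <- c("apl", "agent_mass", "agent_logp", "drag_radius", "box_lx",
               "box_ly", "half_thickness", "eps_water", "eps_membrane",
               "eta_water", "eta_membrane", "temperature", "dt", "n_steps",
               "seed", "z_start", "bin_width", "transfer_sign", "r_min",
               "n_replicates")
.vec_keys <- c("lipid_mean_dipole", "lipid_sd_dipole", "agent_dipole")
.txt_keys <- c("lipid", "lipid_name", "agent", "agent_name", "ke_cap",
               "stop_at_core", "v_start", "output_dir")

.parse_num <- function(key, value, line_no) {
  x <- suppressWarnings(as.numeric(strsplit(value, ",")[[1]]))
  if (anyNA(x))
    stop("param file line ", line_no, ": non-numeric value '", value,
         "' for key '", key, "'")
  x
}

.parse_flag <- function(key, value) {
  v <- tolower(value)
  if (v %in% c("on", "true", "yes", "1")) return(TRUE)
  if (v %in% c("off", "false", "no", "0")) return(FALSE)
  stop("key '", key, "': expected on/off, got '", value, "'")
}

#' Read a parameter file
#'
#' Parses the plain-text `key = value` parameter dialect: one assignment
#' per line, `#` starts a comment, keys are case-insensitive, vector values
#' are comma-separated. A lipid/agent may be given as a preset
#' (`lipid = PC`, `agent = OCT`) or spelled out (`lipid_name`,
#' `lipid_mean_dipole`, `lipid_sd_dipole`, `apl`; `agent_name`,
#' `agent_mass`, `agent_dipole`, `agent_logp`, `drag_radius`). Remaining
#' keys map onto [membrane_geometry()] (`box_lx`, `box_ly`,
#' `half_thickness`), [environment_params()] (`eps_water`, `eps_membrane`,
#' `eta_water`, `eta_membrane`, `temperature`) and [simulation_params()]
#' (`dt`, `n_steps`, `seed`, `z_start`, `bin_width`, `ke_cap`,
#' `transfer_sign`, `stop_at_core`, `v_start`, `r_min`), plus
#' `n_replicates` and `output_dir`. Unknown keys warn; a missing
#' lipid/agent errors with the key name; malformed lines error with their
#' line number.
#'
#' @param path file path.
#' @return A [run_config()].
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    if (!grepl("=", raw, fixed = TRUE))
      stop("param file line ", ln, ": expected 'key = value', got '",
           lines[ln], "'")
    key <- tolower(trimws(sub("=.*$", "", raw)))
    value <- trimws(sub("^[^=]*=", "", raw))
    if (!nzchar(key) || !nzchar(value))
      stop("param file line ", ln, ": empty key or value")
    if (key %in% .num_keys) {
      kv[[key]] <- .parse_num(key, value, ln)
    } else if (key %in% .vec_keys) {
      x <- .parse_num(key, value, ln)
      if (length(x) != 3)
        stop("param file line ", ln, ": key '", key,
             "' needs three comma-separated numbers")
      kv[[key]] <- x
    } else if (key %in% .txt_keys) {
      kv[[key]] <- value
    } else {
      warning("param file line ", ln, ": unknown key '", key,
              "' ignored")
    }
  }
  pick <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default

  apl <- pick("apl", 64)
  lipid <- if (!is.null(kv$lipid)) {
    preset_lipid(kv$lipid, apl = apl)
  } else if (!is.null(kv$lipid_mean_dipole)) {
    if (is.null(kv$lipid_sd_dipole))
      stop("missing required key 'lipid_sd_dipole'")
    lipid_spec(pick("lipid_name", "custom"), kv$lipid_mean_dipole,
               kv$lipid_sd_dipole, apl = apl)
  } else {
    stop("missing required key 'lipid' (preset) or 'lipid_mean_dipole'")
  }
  agent <- if (!is.null(kv$agent)) {
    preset_agent(kv$agent, drag_radius = pick("drag_radius", 1e-14))
  } else if (!is.null(kv$agent_dipole)) {
    if (is.null(kv$agent_mass)) stop("missing required key 'agent_mass'")
    if (is.null(kv$agent_logp)) stop("missing required key 'agent_logp'")
    agent_spec(pick("agent_name", "custom"), kv$agent_mass,
               kv$agent_dipole, kv$agent_logp,
               drag_radius = pick("drag_radius", 1e-14))
  } else {
    stop("missing required key 'agent' (preset) or 'agent_dipole'")
  }
  geometry <- membrane_geometry(pick("box_lx", 80), pick("box_ly", 80),
                                pick("half_thickness", 20))
  env <- environment_params(pick("eps_water", 88), pick("eps_membrane", 4),
                            pick("eta_water", 0.89e-3),
                            pick("eta_membrane", 934e-3),
                            pick("temperature", 300))
  sim <- simulation_params(
    dt = pick("dt", 1e-15), n_steps = pick("n_steps", 5e5),
    seed = pick("seed", 1), z_start = pick("z_start", 45),
    temperature = pick("temperature", 300),
    bin_width = pick("bin_width", 0.2),
    ke_cap = if (!is.null(kv$ke_cap)) .parse_flag("ke_cap", kv$ke_cap)
             else TRUE,
    transfer_sign = pick("transfer_sign", 1),
    stop_at_core = if (!is.null(kv$stop_at_core))
      .parse_flag("stop_at_core", kv$stop_at_core) else TRUE,
    v_start = pick("v_start", "thermal"), r_min = pick("r_min", 1))
  run_config(lipid, agent, geometry, env, sim,
             n_replicates = pick("n_replicates", 1),
             output_dir = pick("output_dir", "."))
}

#' Write a parameter file
#'
#' Serialises a [run_config()] to the `key = value` dialect read by
#' [read_params()]; the lipid and agent are always spelled out in full so
#' the round trip is lossless.
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = ", ")
  flag <- function(x) if (isTRUE(x)) "on" else "off"
  l <- config$lipid; a <- config$agent; g <- config$geometry
  e <- config$env; s <- config$sim
  lines <- c(
    "# dipscreen parameter file",
    paste0("lipid_name = ", l$name),
    paste0("lipid_mean_dipole = ", num(l$mean_dipole)),
    paste0("lipid_sd_dipole = ", num(l$sd_dipole)),
    paste0("apl = ", num(l$apl)),
    paste0("agent_name = ", a$name),
    paste0("agent_mass = ", num(a$mass)),
    paste0("agent_dipole = ", num(a$dipole)),
    paste0("agent_logp = ", num(a$logp)),
    paste0("drag_radius = ", num(a$drag_radius)),
    paste0("box_lx = ", num(g$lx)),
    paste0("box_ly = ", num(g$ly)),
    paste0("half_thickness = ", num(g$half_thickness)),
    paste0("eps_water = ", num(e$eps_r_water)),
    paste0("eps_membrane = ", num(e$eps_r_membrane)),
    paste0("eta_water = ", num(e$eta_water)),
    paste0("eta_membrane = ", num(e$eta_membrane)),
    paste0("temperature = ", num(e$temperature)),
    paste0("dt = ", num(s$dt)),
    paste0("n_steps = ", num(s$n_steps)),
    paste0("seed = ", num(s$seed)),
    paste0("z_start = ", num(s$z_start)),
    paste0("bin_width = ", num(s$bin_width)),
    paste0("ke_cap = ", flag(s$ke_cap)),
    paste0("transfer_sign = ", num(s$transfer_sign)),
    paste0("stop_at_core = ", flag(s$stop_at_core)),
    paste0("v_start = ", s$v_start),
    paste0("r_min = ", num(s$r_min)),
    paste0("n_replicates = ", num(config$n_replicates)),
    paste0("output_dir = ", config$output_dir)
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- column writers / readers ---------------------------------------------

.write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  txt <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }), sep = " "))
  writeLines(txt, con)
  invisible(path)
}

#' Write / read a membrane site table
#'
#' `membrane.txt` dialect: whitespace-separated columns
#' `x y z mux muy muz` (Angstrom, Debye), one site per line, `#`-prefixed
#' header, full double precision.
#'
#' @param membrane a `membrane` object.
#' @param path file path.
#' @return `write_membrane`: `path` invisibly. `read_membrane`: a
#'   `membrane` object (geometry reconstructed from the site extents; seed
#'   unknown).
#' @export
write_membrane <- function(membrane, path) {
  stopifnot(inherits(membrane, "membrane"))
  g <- membrane$geometry
  hdr <- c("# dipscreen membrane sites",
           sprintf("# box %.17g %.17g half_thickness %.17g",
                   g$lx, g$ly, g$half_thickness),
           "# x[A] y[A] z[A] mux[D] muy[D] muz[D]")
  .write_table(membrane$sites, path, hdr)
}

#' @rdname write_membrane
#' @export
read_membrane <- function(path) {
  if (!file.exists(path)) stop("membrane file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  box <- grep("^# box ", lines, value = TRUE)
  tab <- .read_columns(path, 6)
  names(tab) <- c("x", "y", "z", "mux", "muy", "muz")
  geometry <- if (length(box) == 1) {
    v <- suppressWarnings(
      as.numeric(regmatches(box, gregexpr("[-+0-9.eE]+", box))[[1]]))
    v <- v[!is.na(v)]
    membrane_geometry(v[1], v[2], v[3])
  } else {
    membrane_geometry(max(tab$x) + min(tab$x), max(tab$y) + min(tab$y),
                      max(abs(tab$z)))
  }
  structure(list(sites = tab, geometry = geometry, lipid = NULL,
                 seed = NA_integer_, eps_r_inside = 4.0,
                 eta_inside = 0.934),
            class = "membrane")
}

#' Write a trajectory table
#'
#' `data.txt` dialect: columns `step time x y z` (`time` in seconds,
#' positions in Angstrom), `#`-prefixed header, one line per recorded step.
#'
#' @param trajectory a `trajectory` from [run_trajectory()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  hdr <- c("# dipscreen agent trajectory",
           "# step time[s] x[A] y[A] z[A]")
  .write_table(trajectory[, c("step", "time", "x", "y", "z")], path, hdr)
}

#' Write / read a free-energy profile
#'
#' `energy.txt` dialect: two whitespace-separated columns, `z` (Angstrom)
#' and `dG` (kcal/mol), `#`-prefixed header; unsampled bins are omitted.
#' `read_external_profile` also reads profiles produced elsewhere (e.g. by
#' molecular-dynamics free-energy codes) on their native grid; `#`
#' comments and blank lines are allowed, ragged rows raise an error with
#' their row number.
#'
#' @param profile an `fe_profile`.
#' @param path file path.
#' @param rezero_bulk logical: re-zero the external profile at its largest
#'   z (the bulk end)? Default FALSE.
#' @return `write_profile`: `path` invisibly. `read_external_profile`: an
#'   `fe_profile` on the file's native grid.
#' @export
write_profile <- function(profile, path) {
  hdr <- c("# dipscreen free-energy profile along the bilayer normal",
           "# z[A] dG[kcal/mol]")
  keep <- !is.na(profile$dg)
  .write_table(data.frame(z = profile$z[keep], dg = profile$dg[keep]),
               path, hdr)
}

.read_columns <- function(path, ncol_expected) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(sub("#.*$", "", lines[ln]))
    if (!nzchar(raw)) next
    fields <- strsplit(raw, "[[:space:]]+")[[1]]
    if (length(fields) != ncol_expected)
      stop("row ", ln, ": expected ", ncol_expected, " columns, found ",
           length(fields))
    x <- suppressWarnings(as.numeric(fields))
    if (anyNA(x)) stop("row ", ln, ": non-numeric field")
    rows[[length(rows) + 1L]] <- x
  }
  if (!length(rows)) stop("no data rows in ", path)
  as.data.frame(do.call(rbind, rows))
}

#' @rdname write_profile
#' @export
read_external_profile <- function(path, rezero_bulk = FALSE) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tab <- .read_columns(path, 2)
  names(tab) <- c("z", "dg")
  tab <- tab[order(tab$z), ]
  rownames(tab) <- NULL
  if (rezero_bulk) tab$dg <- tab$dg - tab$dg[nrow(tab)]
  dz <- diff(tab$z)
  bw <- if (length(dz)) stats::median(dz) else 0.2
  out <- data.frame(z = tab$z, dg = tab$dg,
                    count = rep(1L, nrow(tab)))
  attr(out, "bin_width") <- bw
  attr(out, "z_ref") <- max(tab$z)
  attr(out, "reference") <- "external profile (native grid)"
  class(out) <- c("fe_profile", "data.frame")
  out
}
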