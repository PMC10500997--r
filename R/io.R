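#' Write a chain or trajectory as a trace PDB
#'
#' Fixed-width multi-MODEL PDB with one pseudo-atom per glycosidic-oxygen
#' anchor (atom name `O4`, residue `HEP`) and one per site center (atom name
#' `SIT`), 1-based residue numbering, chain id `A`.  Anchor `k` carries
#' residue number `k`; site `i` carries residue number `i`.  Coordinates are
#' written at the standard PDB precision of 0.001 Angstrom.
#'
#' @param x An `hp_chain`, a `cg_trajectory`, or a list of `hp_chain`s
#'   (one MODEL each).
#' @param path Output file.
#' @param sites Also write the site-center pseudo-atoms (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trace_pdb <- function(x, path, sites = TRUE) {
  chains <- if (inherits(x, "hp_chain")) {
    list(x)
  } else if (inherits(x, "cg_trajectory")) {
    lapply(seq_len(nrow(x$frames)), function(i) frame_chain(x, i))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "hp_chain"))) {
    x
  } else {
    stop("x must be an hp_chain, a cg_trajectory, or a list of hp_chains",
         call. = FALSE)
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  multi <- length(chains) > 1L
  for (m in seq_along(chains)) {
    ch <- chains[[m]]
    if (any(!is.finite(ch$anchors))) stop("non-finite coordinates", call. = FALSE)
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    lines <- character(0)
    for (k in seq_len(ch$dp + 1L)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "O4", "HEP", "A", k, ch$anchors[k, ], "O"))
    }
    if (sites) {
      for (i in seq_len(ch$dp)) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(serial, "SIT", "HEP", "A", i, ch$sites[i, ], "C"))
      }
    }
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_atom_line <- function(serial, name, resname, chain_id, resno, xyz, element) {
  sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain_id, resno,
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
}

#' Read trace-PDB models as chains
#'
#' Extracts the `O4` anchor pseudo-atoms of each MODEL in residue order and
#' rebuilds `hp_chain` objects; any other atoms (sites, or the full atom set
#' of an all-atom file) are ignored, so an all-atom heparin PDB reduces to
#' its anchor trace.
#'
#' @param path PDB file.
#' @param params [cg_params()] supplying charges and head/tail offsets for
#'   the rebuilt chains.
#' @return A list of `hp_chain` objects (one per MODEL; length 1 for a
#'   single-model file).
#' @export
read_trace_pdb <- function(path, params = cg_params()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  model_breaks <- grepl("^ENDMDL", lines)
  model_idx <- cumsum(c(TRUE, model_breaks[-length(model_breaks)]))
  atom <- grepl("^(ATOM  |HETATM)", lines)
  name <- trimws(substr(lines, 13, 16))
  keep <- atom & name == "O4"
  if (!any(keep)) {
    stop("format error: no O4 anchor records found in '", path, "'",
         call. = FALSE)
  }
  resno <- x <- y <- z <- rep(NA_real_, length(lines))
  resno[atom] <- as.integer(substr(lines[atom], 23, 26))
  x[atom] <- as.numeric(substr(lines[atom], 31, 38))
  y[atom] <- as.numeric(substr(lines[atom], 39, 46))
  z[atom] <- as.numeric(substr(lines[atom], 47, 54))
  out <- list()
  for (m in unique(model_idx[keep])) {
    sel <- which(keep & model_idx == m)
    sel <- sel[order(resno[sel])]
    anchors <- cbind(x[sel], y[sel], z[sel])
    if (nrow(anchors) < 3L) {
      stop("format error: fewer than 3 anchors in model", call. = FALSE)
    }
    out[[length(out) + 1L]] <- build_chain(nrow(anchors) - 1L, params,
                                           template = anchors)
  }
  out
}

#' Write / read a run configuration as YAML
#'
#' Round-trips every field of [run_config()] (weights as a named map).
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$weights <- as.list(obj$weights)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  run_config(n_steps = obj$n_steps, dt = obj$dt,
             temperature = obj$temperature, friction = obj$friction,
             seed = obj$seed, snapshot_stride = obj$snapshot_stride,
             weights = unlist(obj$weights), kappa = obj$kappa,
             init_velocities = obj$init_velocities,
             remove_com = obj$remove_com)
}

#' Structured run log
#'
#' Writes a small key-value log (seed, parameter hash, step counts) next to
#' a trajectory for provenance.
#'
#' @param trajectory A `cg_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  cfg <- trajectory$config
  phash <- substr(paste(
    format(unlist(cfg$weights), digits = 12), cfg$kappa, cfg$dt,
    collapse = "|"), 1, 200)
  lines <- c(
    sprintf("seed: %d", trajectory$seed),
    sprintf("n_steps: %d", cfg$n_steps),
    sprintf("dt_fs: %.6g", cfg$dt),
    sprintf("temperature_K: %.6g", cfg$temperature),
    sprintf("friction_per_ps: %.6g", cfg$friction),
    sprintf("kappa: %.6g", cfg$kappa),
    sprintf("dp: %d", trajectory$chain$dp),
    sprintf("frames: %d", nrow(trajectory$frames)),
    sprintf("mean_kinetic_T: %.6g", trajectory$mean_kinetic_T),
    sprintf("config_digest: %s", phash)
  )
  writeLines(lines, path)
  invisible(path)
}
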