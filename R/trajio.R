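#' Build a chromophore trajectory object
#'
#' A trajectory is a tidy tibble with one row per atom per frame and columns
#' `frame`, `time_ps`, `state` (electronic state, one of `"S0"`, `"S1"`,
#' `"S2"`), `label` (role label, e.g. `"D_ring_N"`, `"His278_NE2"`), and
#' Cartesian coordinates `x`, `y`, `z` in angstrom. Frame times must be
#' strictly increasing and uniformly spaced, every frame must carry the same
#' set of unique labels, and `S2` may appear only before the first `S0` frame.
#' Scalar channels that are not represented geometrically (the A--B--C bridge
#' dihedrals D1--D3 of the bilin) ride along as an `aux` attribute, a tibble
#' with columns `frame`, `d1`, `d2`, `d3` in degrees.
#'
#' @param atoms Tibble with columns `frame`, `time_ps`, `state`, `label`,
#'   `x`, `y`, `z`.
#' @param id Trajectory identifier string.
#' @param dt Frame spacing in ps; inferred from the first two frames when
#'   `NULL`.
#' @param aux Optional per-frame tibble of scalar dihedral channels
#'   (`frame`, `d1`, `d2`, `d3`).
#' @return A tibble of class `bilin_trajectory`.
#' @export
new_trajectory <- function(atoms, id, dt = NULL, aux = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("frame", "time_ps", "state", "label", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory atoms are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  times <- unique(atoms[, c("frame", "time_ps")])
  times <- times[order(times$frame), ]
  if (nrow(times) < 2) abort("a trajectory needs at least 2 frames")
  if (any(diff(times$time_ps) <= 0)) {
    bad <- which(diff(times$time_ps) <= 0)[1] + 1L
    abort(paste0("frame times are not strictly increasing at frame ", bad))
  }
  if (is.null(dt)) dt <- times$time_ps[2] - times$time_ps[1]
  out <- atoms[order(atoms$frame), ]
  structure(out,
            class = c("bilin_trajectory", class(tibble())),
            id = as.character(id), dt = dt, aux = aux)
}

validate_trajectory <- function(traj) {
  frames <- split(traj$label, traj$frame)
  ref <- sort(frames[[1]])
  for (i in seq_along(frames)) {
    lab <- frames[[i]]
    if (anyDuplicated(lab)) {
      abort(paste0("duplicate atom labels in frame ", names(frames)[i]))
    }
    if (!identical(sort(lab), ref)) {
      abort(paste0("atom labels in frame ", names(frames)[i],
                   " differ from frame 1"))
    }
  }
  if (!all(is.finite(traj$x) & is.finite(traj$y) & is.finite(traj$z))) {
    abort("non-finite atom positions")
  }
  states <- frame_table(traj)$state
  if (any(states == "S2")) {
    first_s0 <- match("S0", states)
    if (!is.na(first_s0) && any(states[first_s0:length(states)] == "S2")) {
      abort("S2 frames may occur only before the first S0 frame")
    }
  }
  invisible(traj)
}

#' @export
print.bilin_trajectory <- function(x, ...) {
  ft <- frame_table(x)
  cat(sprintf("<bilin_trajectory '%s'>  %d frames, %d atoms/frame, dt = %g ps\n",
              attr(x, "id"), nrow(ft), sum(x$frame == x$frame[1]),
              attr(x, "dt")))
  NextMethod()
}

#' Per-frame summary of a trajectory
#'
#' @param traj A `bilin_trajectory`.
#' @return Tibble with one row per frame: `frame`, `time_ps`, `state`.
#' @export
frame_table <- function(traj) {
  out <- unique(as_tibble(traj)[, c("frame", "time_ps", "state")])
  out[order(out$frame), ]
}

#' Extract positions of one labelled atom across frames
#'
#' @param traj A `bilin_trajectory`.
#' @param label Role label of the atom.
#' @return Matrix with one row per frame, columns x, y, z (angstrom).
#' @export
atom_track <- function(traj, label) {
  rows <- traj[traj$label == label, ]
  if (nrow(rows) == 0) abort(paste0("unknown atom label: ", label))
  rows <- rows[order(rows$frame), ]
  as.matrix(rows[, c("x", "y", "z")])
}

# ---- extended XYZ ----------------------------------------------------------

fmt_num <- function(x) sprintf("%.6f", x)

#' Write a trajectory as multi-frame extended XYZ
#'
#' The comment line of every frame carries `t=<ps> state=<S0|S1|S2>` and,
#' when the trajectory has auxiliary dihedral channels, `d1= d2= d3=` values
#' in degrees. The atom-name column holds the role label. Units are angstrom
#' and picosecond.
#'
#' @param traj A `bilin_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  ft <- frame_table(traj)
  aux <- attr(traj, "aux")
  chunks <- lapply(seq_len(nrow(ft)), function(i) {
    fr <- ft$frame[i]
    at <- traj[traj$frame == fr, ]
    comment <- sprintf("t=%s state=%s", fmt_num(ft$time_ps[i]), ft$state[i])
    if (!is.null(aux)) {
      a <- aux[aux$frame == fr, ]
      comment <- paste0(comment, sprintf(" d1=%s d2=%s d3=%s",
                                         fmt_num(a$d1), fmt_num(a$d2),
                                         fmt_num(a$d3)))
    }
    c(as.character(nrow(at)), comment,
      sprintf("%s %s %s %s", at$label, fmt_num(at$x), fmt_num(at$y),
              fmt_num(at$z)))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Read a multi-frame extended XYZ trajectory
#'
#' Expects the dialect written by [write_xyz_trajectory()]: an atom count
#' line, a comment line `t=<ps> state=<S0|S1|S2>` (optionally with `d1=`,
#' `d2=`, `d3=` channels), then one `label x y z` line per atom. The frame
#' spacing `dt` is inferred from the first two frames.
#'
#' @param path File path.
#' @param id Trajectory id; defaults to the file name without extension.
#' @return A `bilin_trajectory`.
#' @export
read_xyz_trajectory <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > suppressWarnings(max(which(nzchar(lines)), 0)))]
  pos <- 1L
  frame_idx <- 0L
  atoms <- list()
  aux <- list()
  has_aux <- NA
  while (pos <= length(lines)) {
    frame_idx <- frame_idx + 1L
    n_at <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n_at) || n_at <= 0) {
      abort(paste0("malformed atom count at frame ", frame_idx))
    }
    if (pos + 1L + n_at > length(lines) + 0L) {
      abort(paste0("truncated frame ", frame_idx,
                   ": header promises ", n_at, " atoms"))
    }
    comment <- lines[pos + 1L]
    kv <- parse_key_values(comment)
    if (!all(c("t", "state") %in% names(kv))) {
      abort(paste0("comment line of frame ", frame_idx,
                   " lacks t= or state="))
    }
    body <- lines[(pos + 2L):(pos + 1L + n_at)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) != 4L)) {
      abort(paste0("malformed atom line in frame ", frame_idx))
    }
    m <- do.call(rbind, parts)
    xyz <- suppressWarnings(matrix(as.numeric(m[, 2:4]), ncol = 3))
    if (any(!is.finite(xyz))) {
      abort(paste0("non-numeric coordinates in frame ", frame_idx))
    }
    atoms[[frame_idx]] <- tibble(
      frame = frame_idx, time_ps = as.numeric(kv[["t"]]),
      state = kv[["state"]], label = m[, 1],
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    frame_has_aux <- all(c("d1", "d2", "d3") %in% names(kv))
    if (is.na(has_aux)) has_aux <- frame_has_aux
    if (frame_has_aux != has_aux) {
      abort(paste0("frame ", frame_idx,
                   " is inconsistent about d1/d2/d3 channels"))
    }
    if (frame_has_aux) {
      aux[[frame_idx]] <- tibble(frame = frame_idx,
                                 d1 = as.numeric(kv[["d1"]]),
                                 d2 = as.numeric(kv[["d2"]]),
                                 d3 = as.numeric(kv[["d3"]]))
    }
    pos <- pos + 2L + n_at
  }
  at <- bind_rows(atoms)
  traj <- new_trajectory(at, id = id,
                         aux = if (isTRUE(has_aux)) bind_rows(aux) else NULL)
  validate_trajectory(traj)
}

parse_key_values <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

# ---- minimal PDB -----------------------------------------------------------

#' Read a minimal PDB file into a trajectory
#'
#' Only `ATOM`/`HETATM` coordinate records and `MODEL`/`ENDMDL` framing are
#' interpreted. Role labels are reconstructed as
#' `<ResName><resSeq>_<atomName>` for `ATOM` records (e.g. `His278_NE2`),
#' `WAT<resSeq>_O` for water `HETATM` records, and the bare atom name for the
#' chromophore residue (`BLN`). Single-model files are padded to the
#' two-frame minimum only if `MODEL` records are present; otherwise use
#' [read_pdb_frame()].
#'
#' @param path File path.
#' @param id Trajectory id.
#' @param dt Frame spacing in ps assigned to the models (PDB has no time
#'   axis); default 1 ps.
#' @return A `bilin_trajectory`.
#' @export
read_pdb_trajectory <- function(path, id = NULL, dt = 1) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  model_breaks <- grepl("^MODEL", lines)
  frame <- cumsum(model_breaks)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) abort("no ATOM/HETATM records found")
  frame <- frame[keep]
  if (all(frame == 0)) frame <- frame + 1L
  rec <- lines[keep]
  lab <- pdb_role_label(rec)
  at <- tibble(
    frame = as.integer(frame),
    time_ps = (as.integer(frame) - 1L) * dt,
    state = "S0",
    label = lab,
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)))
  validate_trajectory(new_trajectory(at, id = id, dt = dt))
}

#' Read a single PDB model as one labelled frame
#'
#' @inheritParams read_pdb_trajectory
#' @return Tibble with columns `label`, `x`, `y`, `z`.
#' @export
read_pdb_frame <- function(path) {
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(rec) == 0) abort("no ATOM/HETATM records found")
  tibble(label = pdb_role_label(rec),
         x = as.numeric(substr(rec, 31, 38)),
         y = as.numeric(substr(rec, 39, 46)),
         z = as.numeric(substr(rec, 47, 54)))
}

pdb_role_label <- function(rec) {
  name <- trimws(substr(rec, 13, 16))
  resn <- trimws(substr(rec, 18, 20))
  resi <- trimws(substr(rec, 23, 26))
  is_het <- grepl("^HETATM", rec)
  title <- paste0(substr(resn, 1, 1), tolower(substr(resn, 2, nchar(resn))))
  ifelse(resn %in% c("BLN", "BV"), name,
    ifelse(resn %in% c("HOH", "WAT"), paste0("WAT", resi, "_", name),
      paste0(title, resi, "_", name)))
}

#' Write one trajectory frame as a minimal PDB model
#'
#' Inverse of the [read_pdb_frame()] label mapping for labels of the forms
#' `Res123_NAME`, `WAT1_O`, and bare chromophore atom names.
#'
#' @param frame Tibble with columns `label`, `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_frame <- function(frame, path) {
  lab <- frame$label
  m <- regmatches(lab, regexec("^([A-Za-z]{3})(\\d+)_(.+)$", lab))
  lines <- character(nrow(frame))
  for (i in seq_len(nrow(frame))) {
    if (length(m[[i]]) == 4 && !grepl("^WAT", lab[i])) {
      lines[i] <- sprintf("ATOM  %5d %-4s %3s A%4s    %8.3f%8.3f%8.3f",
                          i, substr(m[[i]][4], 1, 4), toupper(m[[i]][2]),
                          m[[i]][3], frame$x[i], frame$y[i], frame$z[i])
    } else if (grepl("^WAT", lab[i])) {
      resi <- sub("^WAT(\\d+)_.*$", "\\1", lab[i])
      lines[i] <- sprintf("HETATM%5d %-4s %3s A%4s    %8.3f%8.3f%8.3f",
                          i, "O", "WAT", resi, frame$x[i], frame$y[i],
                          frame$z[i])
    } else {
      lines[i] <- sprintf("HETATM%5d %-4s %3s A%4s    %8.3f%8.3f%8.3f",
                          i, substr(lab[i], 1, 4), "BLN", "1",
                          frame$x[i], frame$y[i], frame$z[i])
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- hop records -----------------------------------------------------------

#' Read per-trajectory surface-hop records
#'
#' CSV with columns `trajectory_id`, `hop_time_ps` (empty = censored:
#' the trajectory was still in the excited state at `censor_time_ps`),
#' `censor_time_ps`, `reactive`. Censored records must have
#' `reactive = FALSE`.
#'
#' @param path CSV file path.
#' @return Tibble of hop records in file order, with `hop_time_ps = NA` for
#'   censored trajectories.
#' @export
read_hop_records <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    trajectory_id = readr::col_character(),
    hop_time_ps = readr::col_double(),
    censor_time_ps = readr::col_double(),
    reactive = readr::col_logical()), na = c("", "NA"))
  validate_hop_records(out)
}

validate_hop_records <- function(records) {
  records <- as_tibble(records)
  required <- c("trajectory_id", "hop_time_ps", "censor_time_ps", "reactive")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("hop records are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  cens <- is.na(records$hop_time_ps)
  if (any(cens & records$reactive)) {
    bad <- records$trajectory_id[cens & records$reactive][1]
    abort(paste0("censored record marked reactive: ", bad))
  }
  late <- !cens & records$hop_time_ps > records$censor_time_ps
  if (any(late)) {
    abort(paste0("hop_time_ps exceeds censor_time_ps for: ",
                 records$trajectory_id[late][1]))
  }
  records
}

#' Write hop records as CSV
#'
#' Censored hop times are written as empty fields so the censoring state
#' round-trips unambiguously.
#'
#' @param records Hop-record tibble (see [read_hop_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hop_records <- function(records, path) {
  validate_hop_records(records)
  readr::write_csv(records, path, na = "")
  invisible(path)
}

# ---- report ----------------------------------------------------------------

#' Write a deterministic JSON analysis report
#'
#' Scalar results and small tables are serialized with sorted keys and a
#' fixed header (units declaration, no timestamps), so re-running on
#' identical inputs produces byte-identical output. Non-finite values are
#' rejected.
#'
#' @param results Named list of scalars, vectors, and data frames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (length(results) > 0 &&
      (is.null(names(results)) || any(names(results) == ""))) {
    abort("all report entries must be named")
  }
  bad <- names(results)[vapply(results, has_nonfinite, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-finite values in report entries: ",
                 paste(bad, collapse = ", ")))
  }
  if (length(results) > 0) results <- results[order(names(results))]
  payload <- list(
    meta = list(
      generator = "hulatwist",
      units = list(distance = "angstrom", time = "ps", angle = "degree",
                   energy = "kcal/mol")),
    results = results)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", null = "null")
  writeLines(json, path)
  invisible(path)
}

has_nonfinite <- function(x) {
  if (is.data.frame(x)) return(any(vapply(x, has_nonfinite, logical(1))))
  if (is.list(x)) return(any(vapply(x, has_nonfinite, logical(1))))
  if (is.numeric(x)) return(any(!is.finite(x)))
  FALSE
}
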