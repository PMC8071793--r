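#' Write a toy system as PDB plus a nonbonded parameter table
#'
#' The coordinates, residue numbering and chain labels go into a PDB file
#' (coordinates converted from nm to Angstrom); the per-atom nonbonded
#' parameters go into a comma-delimited table with columns `atom_serial`,
#' `charge_e`, `sigma_nm`, `epsilon_kJmol`, `group` and `molecule_id`.
#'
#' @param system a [toy_system].
#' @param pdb_file,param_file output paths.
#' @return invisibly, a list with both paths.
#' @export
write_system <- function(system, pdb_file, param_file) {
  n <- nrow(system$positions)
  chain <- rep("X", n)
  if (!is.null(system$chain)) {
    ch <- system$chain[system$residue]
    chain <- ifelse(ch %in% c("A", "B"), ch, "X")
  }
  bio3d::write.pdb(file = pdb_file,
                   xyz = as.vector(t(system$positions)) * 10,
                   resno = system$residue,
                   chain = chain,
                   resid = ifelse(system$group == "protein", "ALA", "LIP"),
                   elety = rep("C", n))
  utils::write.csv(
    data.frame(atom_serial = seq_len(n), charge_e = system$charge,
               sigma_nm = system$sigma, epsilon_kJmol = system$epsilon,
               group = system$group, molecule_id = system$molecule),
    param_file, row.names = FALSE)
  invisible(list(pdb = pdb_file, params = param_file))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param frames list of N x 3 coordinate matrices (nm).
#' @param system a [toy_system] supplying residue numbering and chains.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_trajectory_pdb <- function(frames, system, file) {
  n <- nrow(system$positions)
  chain <- rep("X", n)
  if (!is.null(system$chain)) {
    ch <- system$chain[system$residue]
    chain <- ifelse(ch %in% c("A", "B"), ch, "X")
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (t in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", t), con)
    xyz <- as.matrix(frames[[t]]) * 10
    lines <- sprintf(
      "ATOM  %5d  C   %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n), ifelse(system$group == "protein", "ALA", "LIP"),
      chain, system$residue, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read coordinates from a PDB or GRO file
#'
#' PDB files (including multi-model trajectories) are read with bio3d and
#' converted to nm; GRO files are parsed directly (they are already in nm).
#'
#' @param file path to a `.pdb` or `.gro` file.
#' @return for a single structure, an N x 3 matrix (nm) with attribute
#'   `meta` (data.frame: residue, chain); for a multi-model PDB, a list of
#'   such matrices (the attribute on the first element).
#' @export
read_coordinates <- function(file) {
  if (grepl("\\.gro$", file, ignore.case = TRUE)) return(read_gro(file))
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  meta <- data.frame(residue = pdb$atom$resno, chain = pdb$atom$chain,
                     stringsAsFactors = FALSE)
  nmodel <- nrow(pdb$xyz)
  to_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE) / 10
  if (is.null(nmodel) || nmodel == 1L) {
    out <- to_mat(pdb$xyz[1, ])
    attr(out, "meta") <- meta
    return(out)
  }
  frames <- lapply(seq_len(nmodel), function(i) to_mat(pdb$xyz[i, ]))
  attr(frames[[1]], "meta") <- meta
  frames
}

# Minimal fixed-format GRO reader (single frame, orthorhombic box).
read_gro <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  residue <- as.integer(substr(body, 1, 5))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  out <- cbind(x, y, z)
  attr(out, "meta") <- data.frame(residue = residue, chain = NA_character_,
                                  stringsAsFactors = FALSE)
  attr(out, "box") <- box
  out
}

#' Assemble a system from a coordinate file and a parameter table
#'
#' @param coord_file PDB or GRO file with one frame.
#' @param param_file delimited parameter table as written by
#'   [write_system()].
#' @param box orthorhombic box lengths (nm); taken from the GRO box record
#'   when omitted and available.
#' @return a [toy_system].
#' @export
system_from_files <- function(coord_file, param_file, box = NULL) {
  pos <- read_coordinates(coord_file)
  if (is.list(pos)) stop("expected a single-frame coordinate file",
                         call. = FALSE)
  meta <- attr(pos, "meta")
  if (is.null(box)) box <- attr(pos, "box")
  if (is.null(box)) stop("box must be given for PDB input", call. = FALSE)
  par <- utils::read.csv(param_file, stringsAsFactors = FALSE)
  need <- c("charge_e", "sigma_nm", "epsilon_kJmol", "group", "molecule_id")
  if (!all(need %in% names(par))) {
    stop("parameter table lacks columns: ",
         paste(setdiff(need, names(par)), collapse = ", "), call. = FALSE)
  }
  if (nrow(par) != nrow(pos)) {
    stop("parameter table and coordinates disagree on atom count",
         call. = FALSE)
  }
  chain <- NULL
  if (!all(is.na(meta$chain))) {
    chain <- rep("none", max(meta$residue))
    pr <- !duplicated(meta$residue)
    chain[meta$residue[pr]] <- ifelse(meta$chain[pr] %in% c("A", "B"),
                                      meta$chain[pr], "none")
  }
  toy_system(positions = unclass(pos)[, 1:3], charge = par$charge_e,
             sigma = par$sigma_nm, epsilon = par$epsilon_kJmol,
             residue = meta$residue, molecule = par$molecule_id,
             group = par$group, chain = chain, box = box)
}

#' Write a punctual-stress series as a delimited matrix
#'
#' First columns `frame` and `time_ps`, then one column per residue with a
#' `chain:residue` header.
#'
#' @param series a `punctual_stress_series`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_stress_series <- function(series, file) {
  df <- data.frame(frame = seq_len(nrow(series$values)) - 1,
                   time_ps = series$frame_times)
  mat <- as.data.frame(series$values)
  names(mat) <- paste0(series$residue_ids$chain, ":",
                       series$residue_ids$residue)
  utils::write.csv(cbind(df, mat), file, row.names = FALSE)
  invisible(file)
}

#' Read a punctual-stress series written by [write_stress_series()]
#'
#' @param file path.
#' @return a `punctual_stress_series`.
#' @export
read_stress_series <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  rescols <- setdiff(names(df), c("frame", "time_ps"))
  parts <- strsplit(rescols, ":", fixed = TRUE)
  structure(list(values = as.matrix(df[, rescols, drop = FALSE]),
                 residue_ids = data.frame(
                   residue = as.integer(vapply(parts, `[`, "", 2)),
                   chain = vapply(parts, `[`, "", 1),
                   stringsAsFactors = FALSE),
                 frame_times = df$time_ps),
            class = "punctual_stress_series")
}

#' Write per-residue values into the B-factor column of a PDB
#'
#' Color-by-attribute aid for external molecular viewers: each atom's
#' B-factor is set to the value of its residue (e.g. mean punctual stress
#' or a PLS coefficient).
#'
#' @param system a [toy_system].
#' @param values named or positional per-residue values (one per protein
#'   residue, increasing residue order).
#' @param file output PDB path.
#' @return invisibly, `file`.
#' @export
write_residue_pdb <- function(system, values, file) {
  res <- sort(unique(system$residue[system$group == "protein"]))
  if (length(values) != length(res)) {
    stop("need one value per protein residue", call. = FALSE)
  }
  b <- numeric(nrow(system$positions))
  for (i in seq_along(res)) b[system$residue == res[i]] <- values[i]
  n <- nrow(system$positions)
  chain <- rep("X", n)
  if (!is.null(system$chain)) {
    ch <- system$chain[system$residue]
    chain <- ifelse(ch %in% c("A", "B"), ch, "X")
  }
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(system$positions)) * 10,
                   resno = system$residue, chain = chain,
                   resid = ifelse(system$group == "protein", "ALA", "LIP"),
                   elety = rep("C", n), b = b)
  invisible(file)
}
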