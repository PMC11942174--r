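#' Read a PDB file into a topology and coordinates
#'
#' Parsing is delegated to bio3d; the result is repackaged into the
#' package's [md_topology()] container.  Residue ids stay 1-based as in
#' the file and insertion codes are retained in the atom table.  Elements
#' come from the element columns when present; otherwise they are
#' inferred from the atom name (with a warning).
#'
#' @param path PDB file.
#' @return list: `topology` ([md_topology()]), `coords` (`n x 3` matrix,
#'   Angstrom).
#' @export
read_pdb_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    warning(sum(missing_el),
            " atom(s) lack element columns; inferring from atom names")
    element[missing_el] <- .element_from_name(at$elety[missing_el])
  }
  mass_tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                P = 30.974, S = 32.06, CL = 35.45, BR = 79.904, I = 126.9,
                K = 39.098, FE = 55.845, ZN = 65.38, MG = 24.305,
                "NA" = 22.99)
  mass <- unname(mass_tab[element])
  mass[is.na(mass)] <- 12.011
  atoms <- data.frame(atom_id = at$eleno, name = trimws(at$elety),
                      element = element, mass = mass,
                      resid = at$resno, resname = trimws(at$resid),
                      chain = at$chain,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      stringsAsFactors = FALSE)
  list(topology = md_topology(atoms),
       coords = matrix(pdb$xyz, ncol = 3, byrow = TRUE,
                       dimnames = list(NULL, c("x", "y", "z"))))
}

.element_from_name <- function(names) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CU", "SE")
  vapply(names, function(nm) {
    nm <- toupper(gsub("[^A-Za-z]", "", trimws(nm)))
    if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% two) return(substr(nm, 1, 2))
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Write a topology + coordinate set as PDB
#'
#' @param topology an [md_topology()].
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_topology <- function(topology, coords, path) {
  at <- topology$atoms
  stopifnot(nrow(at) == nrow(coords))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords)),
                   type = "ATOM",
                   eleno = at$atom_id, elety = at$name,
                   resid = at$resname, chain = at$chain,
                   resno = at$resid, elesy = at$element)
  invisible(path)
}

#' Write a trajectory ensemble as multi-frame XYZ files
#'
#' One file per run in the plain XYZ convention: per frame, an atom-count
#' line, a comment line (`run <r> frame <f>`), then `element x y z`
#' records in Angstrom.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param topology the shared [md_topology()] (provides elements).
#' @param dir output directory.
#' @param prefix file-name prefix; files are `<prefix>_run<i>.xyz`.
#' @return character vector of file paths, invisibly.
#' @export
write_xyz_frames <- function(ensemble, topology, dir, prefix = "traj") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- topology$atoms$element
  paths <- character(length(ensemble$runs))
  for (r in seq_along(ensemble$runs)) {
    arr <- ensemble$runs[[r]]
    con <- file.path(dir, sprintf("%s_run%d.xyz", prefix, r))
    lines <- character(0)
    for (f in seq_len(dim(arr)[1])) {
      lines <- c(lines, as.character(dim(arr)[2]),
                 sprintf("run %d frame %d", r, f),
                 sprintf("%s %.6f %.6f %.6f", el, arr[f, , 1],
                         arr[f, , 2], arr[f, , 3]))
    }
    writeLines(lines, con)
    paths[r] <- con
  }
  invisible(paths)
}

#' Read multi-frame XYZ files into a trajectory ensemble
#'
#' @param paths one XYZ file per run, in run order.
#' @param topology optional [md_topology()]; frame atom counts must match
#'   it when given.
#' @return a [trajectory_ensemble()] (runs may differ in frame count).
#' @export
read_xyz_frames <- function(paths, topology = NULL) {
  runs <- vector("list", length(paths))
  for (r in seq_along(paths)) {
    lines <- readLines(paths[r])
    i <- 1L; frames <- list()
    while (i <= length(lines)) {
      if (!grepl("^\\s*\\d+\\s*$", lines[i]))
        stop("run ", r, ": expected atom-count line at line ", i,
             " of ", paths[r])
      nat <- as.integer(lines[i])
      if (i + 1L + nat > length(lines))
        stop("run ", r, ": truncated frame starting at line ", i)
      block <- lines[(i + 2L):(i + 1L + nat)]
      parts <- strsplit(trimws(block), "\\s+")
      bad <- which(lengths(parts) < 4)
      if (length(bad))
        stop("run ", r, ": malformed XYZ record at line ", i + 1L + bad[1])
      xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      if (!is.null(topology) && nat != nrow(topology$atoms))
        stop("run ", r, ", frame ", length(frames) + 1L,
             ": atom count ", nat, " does not match topology (",
             nrow(topology$atoms), ")")
      frames[[length(frames) + 1L]] <- xyz
      i <- i + 2L + nat
    }
    arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
    for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
    runs[[r]] <- arr
  }
  # runs of one ensemble must agree on atom count even without a topology
  nat <- vapply(runs, function(a) dim(a)[2], integer(1))
  if (length(unique(nat)) > 1)
    stop("runs disagree on atom count: ", paste(nat, collapse = ", "))
  trajectory_ensemble(runs)
}

#' Write / read the efflux plate CSV schema
#'
#' Columns: condition, dose_uM, technical_rep, biological_rep,
#' efflux_signal, lysate_signal, is_untransfected.  Doses are µM
#' throughout.
#'
#' @param wells plate data.frame (as from [gen_plate()]).
#' @param path CSV file.
#' @return `path` (write) / the plate data.frame (read).
#' @export
write_plate_csv <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "dose_uM", "technical_rep", "biological_rep",
            "efflux_signal", "lysate_signal", "is_untransfected")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("plate CSV lacks column(s): ", paste(miss, collapse = ", "))
  wells$is_untransfected <- as.logical(wells$is_untransfected)
  wells
}

#' Write / read the fingerprint library TSV schema
#'
#' Columns: `compound_id`, `score`, `bits` (sorted space-separated on-bit
#' indices).
#'
#' @param library an [fp_library()].
#' @param path TSV file.
#' @return `path` (write) / an [fp_library()] (read).
#' @export
write_fingerprint_tsv <- function(library, path) {
  df <- data.frame(compound_id = library$compound_id,
                   score = library$score,
                   bits = vapply(library$bits, paste, character(1),
                                 collapse = " "),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @export
read_fingerprint_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(bits = "character"))
  need <- c("compound_id", "score", "bits")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fingerprint TSV lacks column(s): ", paste(miss, collapse = ", "))
  bits <- lapply(strsplit(df$bits, "\\s+"), function(b)
    as.integer(b[b != ""]))
  fp_library(df$compound_id, bits, df$score)
}
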