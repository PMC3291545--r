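# Reading and writing structures, poses and sites.
#
# Atom tables are plain tibbles with one row per atom:
#   serial, name, resid, chain, resno, x, y, z, element, record_kind
# plus logical role columns (is_donor, is_acceptor, is_carbon, is_aromatic,
# is_polar_h) once assign_roles() has been applied.  All coordinates are
# Cartesian angstroms; only the oxygen position of a water is ever used.

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SPC")
ION_RESIDS <- c(
  "NA", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI", "CO", "CD",
  "LI", "CS", "CL", "BR", "IOD", "FE2", "SO4", "PO4"
)
METAL_ELEMENTS <- c(
  "NA", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI", "CO", "CD", "LI", "CS"
)

#' Read a PDB file into an atom tibble
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d) and classifies each
#' atom as protein, water, ion, cofactor or ligand.  Waters are recognised
#' by residue name (HOH/WAT/DOD and common model-water names); ions by
#' residue or element.  Only the first alternate location is kept.
#'
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @param ligand_resid Character vector of residue names to mark as ligand
#'   rather than cofactor.
#' @return A tibble with one row per atom and columns `serial`, `name`,
#'   `resid`, `chain`, `resno`, `x`, `y`, `z`, `element`, `record_kind`.
#'   The structure id is stored in the `"structure_id"` attribute.
#' @export
#' @examples
#' pdb <- system.file("extdata", "pocket_demo.pdb", package = "waterplace")
#' if (nzchar(pdb)) read_pdb(pdb)
read_pdb <- function(path, id = NULL, ligand_resid = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0) {
    abort(paste0("no ATOM/HETATM records in ", path))
  }
  # validate the fixed-column coordinate fields before handing to bio3d so
  # parse failures can name the offending line
  for (i in rec) {
    ln <- lines[[i]]
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (nchar(ln) < 54 || anyNA(coords)) {
      abort(sprintf("malformed ATOM/HETATM record at line %d of %s", i, path))
    }
  }

  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  a <- pdb$atom
  # first altloc only
  keep <- a$alt %in% c("", " ", NA) | !duplicated(paste(a$resno, a$chain, a$elety))
  a <- a[keep, , drop = FALSE]

  element <- toupper(trimws(a$elesy))
  miss <- is.na(element) | element == ""
  if (any(miss)) element[miss] <- guess_element(a$elety[miss])

  resid <- toupper(trimws(a$resid))
  kind <- dplyr::case_when(
    resid %in% WATER_RESIDS ~ "water",
    !is.null(ligand_resid) & resid %in% (ligand_resid %||% "") ~ "ligand",
    a$type == "ATOM" ~ "protein",
    resid %in% ION_RESIDS | element %in% METAL_ELEMENTS ~ "ion",
    TRUE ~ "cofactor"
  )

  atoms <- tibble(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    resid = resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    element = element,
    record_kind = kind
  )
  if (anyDuplicated(atoms$serial)) {
    dup <- atoms$serial[duplicated(atoms$serial)][1]
    abort(sprintf("duplicate atom serial %d in %s", dup, path))
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("non-finite coordinates in PDB file")
  }
  attr(atoms, "structure_id") <- id %||% sub("\\.[^.]+$", "", basename(path))
  atoms
}

# element symbol from an atom name: strip digits/primes, handle two-letter
# elements left-justified in PDBQT-ish files
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Z]", "", toupper(trimws(name))))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "MN", "FE", "CA") &
           nchar(nm) == 2,
         two, substr(nm, 1, 1))
}

#' Read a docked water-pose ensemble
#'
#' Reads one or more pose files and pools them into a single pose table.
#' Two dialects are supported: multi-model PDBQT as written by AutoDock
#' Vina (MODEL blocks whose `REMARK VINA RESULT` line carries the score in
#' kcal/mol as its first numeric field) and a JSON dialect of
#' `{"position": [x, y, z], "score": s, "run": r}` objects.
#'
#' @param paths Character vector of pose files, one per docking run for
#'   PDBQT input.  Run indices follow file order unless the JSON records
#'   carry their own `run` field.
#' @param format `"auto"` (by extension), `"pdbqt"` or `"json"`.
#' @param per_run_cap Number of modes the docking engine can emit per run;
#'   more models than this in one file triggers a warning.
#' @return A tibble of poses: `x`, `y`, `z`, `score` (kcal/mol), `run`,
#'   `mode`.  Model order within each run is preserved.
#' @export
read_pose_ensemble <- function(paths, format = c("auto", "pdbqt", "json"),
                               per_run_cap = 20) {
  format <- arg_match(format)
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (grepl("\\.json$", paths[[i]], ignore.case = TRUE)) "json" else "pdbqt"
    }
    out[[i]] <- switch(fmt,
      pdbqt = parse_pdbqt_poses(paths[[i]], run = i, per_run_cap = per_run_cap),
      json = parse_json_poses(paths[[i]], run = i)
    )
  }
  dplyr::bind_rows(out)
}

parse_pdbqt_poses <- function(path, run, per_run_cap = 20) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    if (any(grepl("^(ATOM|HETATM)", lines))) {
      starts <- 1L
      ends <- length(lines)
    } else {
      return(tibble(x = double(), y = double(), z = double(),
                    score = double(), run = integer(), mode = integer()))
    }
  } else {
    ends <- c(starts[-1] - 1L, length(lines))
  }
  if (length(starts) > per_run_cap) {
    warn(sprintf("%s holds %d models, more than the engine cap of %d per run",
                 basename(path), length(starts), per_run_cap))
  }
  poses <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    block <- lines[starts[m]:ends[m]]
    res <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (length(res) == 0) {
      abort(sprintf("model %d in %s has no 'REMARK VINA RESULT' line", m, path))
    }
    fields <- strsplit(sub("^REMARK VINA RESULT:\\s*", "", res[[1]]), "\\s+")[[1]]
    score <- suppressWarnings(as.numeric(fields[[1]]))
    if (!is.finite(score)) {
      abort(sprintf("unreadable score in model %d of %s", m, path))
    }
    at <- grep("^(ATOM|HETATM)", block, value = TRUE)
    if (length(at) == 0) {
      abort(sprintf("model %d in %s has no atom record", m, path))
    }
    # oxygen position only; hydrogens, if present, are ignored
    el <- guess_element(substr(at, 13, 16))
    ox <- at[el == "O"]
    ln <- if (length(ox) > 0) ox[[1]] else at[[1]]
    poses[[m]] <- tibble(
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      score = score, run = as.integer(run), mode = m
    )
  }
  dplyr::bind_rows(poses)
}

parse_json_poses <- function(path, run) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(recs) == 0) {
    return(tibble(x = double(), y = double(), z = double(),
                  score = double(), run = integer(), mode = integer()))
  }
  purrr::imap(recs, function(r, m) {
    tibble(
      x = r$position[[1]], y = r$position[[2]], z = r$position[[3]],
      score = as.numeric(r$score),
      run = as.integer(r$run %||% run),
      mode = as.integer(m)
    )
  }) |> dplyr::bind_rows()
}

#' Default donor/acceptor role rules
#'
#' The shipped rule table keys hydrogen-bond roles (and aromaticity) on
#' residue + atom name, with `residue == "*"` rows providing element-level
#' fallbacks.  Edit the TSV (or pass your own tibble) to change the
#' chemistry.
#'
#' @param path Optional path to a tab-separated rule file with columns
#'   `residue`, `atom`, `donor`, `acceptor`, `aromatic`.
#' @return A tibble of role rules.
#' @export
read_role_rules <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "role_rules.tsv", package = "waterplace")
  rules <- as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                                stringsAsFactors = FALSE,
                                colClasses = c(
                                  residue = "character", atom = "character",
                                  donor = "integer", acceptor = "integer",
                                  aromatic = "integer"
                                )))
  rules
}

#' Assign chemical roles to atoms
#'
#' Flags every atom with the roles the scoring functions need:
#' hydrogen-bond donor/acceptor (table lookup by residue + atom name, with
#' an element-level fallback for names absent from the table), carbon,
#' aromaticity and polar hydrogens (H within 1.2 A of N/O).  Metals keep
#' `record_kind == "ion"` and get no donor/acceptor flags.
#'
#' @param atoms Atom tibble from [read_pdb()].
#' @param rules Role-rule tibble, see [read_role_rules()].
#' @param quiet Suppress the note about element-level fallbacks.
#' @return The atom tibble with logical columns `is_donor`, `is_acceptor`,
#'   `is_carbon`, `is_aromatic`, `is_polar_h` added.
#' @export
assign_roles <- function(atoms, rules = read_role_rules(), quiet = FALSE) {
  stopifnot(is.data.frame(atoms), all(c("element", "name") %in% names(atoms)))
  n <- nrow(atoms)
  donor <- logical(n); acceptor <- logical(n); aromatic <- logical(n)

  specific <- rules[rules$residue != "*", , drop = FALSE]
  fallback <- rules[rules$residue == "*", , drop = FALSE]

  key <- paste(atoms$resid, atoms$name)
  skey <- paste(specific$residue, specific$atom)
  hit <- match(key, skey)
  got <- !is.na(hit)
  donor[got] <- specific$donor[hit[got]] == 1
  acceptor[got] <- specific$acceptor[hit[got]] == 1
  aromatic[got] <- specific$aromatic[hit[got]] == 1

  # element fallback for polar atoms the table does not name
  need <- !got & atoms$element %in% fallback$atom &
    atoms$record_kind != "ion"
  if (any(need)) {
    fhit <- match(atoms$element[need], fallback$atom)
    donor[need] <- fallback$donor[fhit] == 1
    acceptor[need] <- fallback$acceptor[fhit] == 1
    n_polar_fb <- sum(need & atoms$element %in% c("N", "O", "S"))
    if (!quiet && n_polar_fb > 0) {
      inform(sprintf(
        "assign_roles: %d polar atom(s) not in the rule table; used element-level defaults",
        n_polar_fb
      ))
    }
  }

  is_metal <- atoms$record_kind == "ion" | atoms$element %in% METAL_ELEMENTS
  donor[is_metal] <- FALSE
  acceptor[is_metal] <- FALSE

  atoms$record_kind[atoms$element %in% METAL_ELEMENTS] <- "ion"
  atoms$is_donor <- donor
  atoms$is_acceptor <- acceptor
  atoms$is_carbon <- atoms$element == "C"
  atoms$is_aromatic <- aromatic

  # polar hydrogen: H within covalent range of an N/O
  ph <- logical(n)
  hy <- which(atoms$element == "H")
  no <- which(atoms$element %in% c("N", "O"))
  if (length(hy) > 0 && length(no) > 0) {
    d <- cross_dist(atoms[hy, ], atoms[no, ])
    ph[hy] <- apply(d, 1, min) <= 1.2
  }
  atoms$is_polar_h <- ph
  atoms
}

#' Write predicted hydration sites as a PDB file
#'
#' One HETATM water-oxygen record per site; the B-factor column carries the
#' site's energy score (kcal/mol) when present, for colouring in molecular
#' viewers.  Coordinates round-trip through [read_pdb()] to 0.001 A.
#'
#' @param sites Site tibble with columns `x`, `y`, `z` and optionally
#'   `energy`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_pdb <- function(sites, path) {
  stopifnot(is.data.frame(sites))
  lines <- c("REMARK   1 PREDICTED HYDRATION SITES")
  if (nrow(sites) > 0) {
    bf <- if ("energy" %in% names(sites)) sites$energy else rep(0, nrow(sites))
    bf <- pmin(pmax(bf, -99.99), 999.99)
    recs <- sprintf(
      "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
      seq_len(nrow(sites)), seq_len(nrow(sites)),
      sites$x, sites$y, sites$z, 1.00, bf
    )
    lines <- c(lines, recs)
  }
  lines <- c(lines, "END")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write an atom tibble as a PDB file
#'
#' Minimal fixed-column writer used by the synthetic-fixture generators;
#' round-trips through [read_pdb()] to 0.001 A.
#'
#' @param atoms Atom tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path) {
  rec <- ifelse(atoms$record_kind == "protein", "ATOM  ", "HETATM")
  nm <- ifelse(nchar(atoms$name) < 4, sprintf(" %-3s", atoms$name),
               substr(atoms$name, 1, 4))
  lines <- sprintf(
    "%s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, atoms$serial, nm, substr(atoms$resid, 1, 3),
    substr(atoms$chain, 1, 1), atoms$resno,
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
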