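#' Molecular graph objects
#'
#' A `mol_graph` is the light-weight molecule container used throughout the
#' package: a table of atoms (element symbol, formal charge), a table of bonds
#' (1-based atom indices `i < j`, integer bond order, in-ring flag), an
#' optional `n x 3` matrix of Cartesian coordinates in Angstrom, and a name.
#' Atom indexing is 1-based everywhere, in files and in reports, matching
#' chemical drawing conventions.
#'
#' @param atoms data.frame with columns `element` (character) and `charge`
#'   (integer formal charge).
#' @param bonds data.frame with columns `i`, `j` (atom indices), `order`
#'   (1, 2, 3; aromatic bonds arrive kekulized from the readers) and
#'   optionally `in_ring` (recomputed if missing).
#' @param coords optional numeric matrix (one row per atom, columns x, y, z).
#' @param name molecule label.
#' @return an object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds, coords = NULL, name = "mol") {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  n <- nrow(atoms)
  if (n < 1L) abort_input("molecule '", name, "' has no atoms")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    ij <- cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    bonds$i <- ij[, 1]; bonds$j <- ij[, 2]
    if (any(bonds$i == bonds$j)) abort_input("self-bond in molecule '", name, "'")
    if (any(bonds$i < 1L | bonds$j > n)) {
      abort_input("bond atom index out of range in molecule '", name, "'")
    }
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L) {
      abort_input("coordinates must be one 3D position per atom ('", name, "')")
    }
  }
  m <- structure(list(atoms = atoms, bonds = bonds, coords = coords,
                      name = name),
                 class = "mol_graph")
  m$bonds$in_ring <- ring_bond_flags(m)
  if (n > 1L && !is_connected(m)) {
    abort_input("molecule record '", name,
                "' is disconnected; supply one connected molecule per record")
  }
  m
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms (%d heavy), %d bonds%s\n",
              x$name, n_atoms(x), length(heavy_atoms(x)), nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 3D"))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

heavy_atoms <- function(mol) which(mol$atoms$element != "H")

# Build an igraph whose vertex ids equal atom indices 1..n exactly.
edge_graph <- function(n, i, j) {
  igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                    as.vector(rbind(i, j)))
}

#' @keywords internal
as_igraph <- function(mol, heavy_only = FALSE) {
  n <- n_atoms(mol)
  b <- mol$bonds
  if (heavy_only) {
    hv <- mol$atoms$element != "H"
    keep <- hv[b$i] & hv[b$j]
    b <- b[keep, , drop = FALSE]
  }
  edge_graph(n, b$i, b$j)
}

is_connected <- function(mol) {
  igraph::is_connected(as_igraph(mol))
}

# A bond is part of a ring iff it is not a bridge of the molecular graph.
ring_bond_flags <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(logical(0))
  g <- edge_graph(n_atoms(mol), b$i, b$j)
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(b))
  flags[as.integer(br)] <- FALSE
  flags
}

# Indices of heavy neighbours of atom k.
heavy_neighbours <- function(mol, k) {
  b <- mol$bonds
  nb <- c(b$j[b$i == k], b$i[b$j == k])
  nb[mol$atoms$element[nb] != "H"]
}

neighbours_of <- function(mol, k) {
  b <- mol$bonds
  c(b$j[b$i == k], b$i[b$j == k])
}

bond_index <- function(mol, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  which(mol$bonds$i == lo & mol$bonds$j == hi)
}

## ---------------------------------------------------------------------------
## Readers and writers (SMILES and SDF/MOL V2000 via ChemmineOB / ChemmineR)
## ---------------------------------------------------------------------------

# Convert one molecule record through OpenBabel.
ob_convert <- function(from, to, text, gen3d = FALSE, add_h = FALSE) {
  opts <- data.frame(names = character(), args = character())
  if (gen3d) opts <- rbind(opts, data.frame(names = "gen3d", args = ""))
  if (add_h) opts <- rbind(opts, data.frame(names = "h", args = ""))
  out <- tryCatch(
    if (nrow(opts)) ChemmineOB::convertFormat(from, to, text, options = opts)
    else ChemmineOB::convertFormat(from, to, text),
    error = function(e) abort_input("structure conversion failed: ",
                                    conditionMessage(e))
  )
  if (!nzchar(out)) abort_input("structure conversion produced no output")
  out
}

# 3D structure generation. The primary route is the ETKDG distance-geometry
# embedder (RDKit, driven through the system `python`), which is fully
# deterministic for a fixed seed; the OpenBabel generator serves as fallback
# when no RDKit-capable python is available (its conformer search draws
# system entropy, so the fallback is not seed-reproducible).
gen3d_sdf <- function(sdf_text, seed = 1L) {
  py <- Sys.which("python")
  script <- system.file("python", "embed_sdf.py", package = "atroposcan")
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(sdf_text, fin)
  if (nzchar(py) && nzchar(script) && rdkit_available()) {
    status <- suppressWarnings(
      system2(py, c(shQuote(script), shQuote(fin), shQuote(fout),
                    as.integer(seed)),
              stdout = FALSE, stderr = FALSE))
    if (!identical(status, 0L) || !file.exists(fout) || !file.size(fout)) {
      abort_input("3D embedding failed (embedder exit status ", status, ")")
    }
    return(paste(readLines(fout, warn = FALSE), collapse = "\n"))
  }
  ob_convert("SDF", "SDF", sdf_text, gen3d = TRUE)
}

rdkit_available <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    py <- Sys.which("python")
    ok <- nzchar(py) && identical(suppressWarnings(
      system2(py, c("-c", shQuote("import rdkit")),
              stdout = FALSE, stderr = FALSE)), 0L)
    cached <<- ok
    ok
  }
})

# Parse the first record of an SDF string into a mol_graph.
sdf_text_to_mol <- function(sdf_text, name = NULL, keep_coords = TRUE) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_text, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
  if (length(sdfs) < 1L) abort_input("no molecule records parsed from SDF")
  sdf_to_mol(sdfs[[1]], name = name, raw_text = sdf_text,
             keep_coords = keep_coords)
}

sdf_to_mol <- function(sdf, name = NULL, raw_text = NULL, keep_coords = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (identical(rownames(ab), "0") && !is.null(raw_text)) {
    # bond-less records (single atoms) come back as a zero stub; fall back
    # to reading the fixed-width V2000 columns directly
    return(parse_v2000_text(raw_text, name = name, keep_coords = keep_coords))
  }
  element <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  charge <- rep(0L, n)
  if (!is.null(raw_text)) {
    chg <- sdf_charges(raw_text)
    if (nrow(chg)) charge[chg$atom] <- chg$charge
  }
  coords <- NULL
  if (keep_coords) {
    xyz <- ab[, 1:3, drop = FALSE]
    if (sdf_is_3d(raw_text, xyz[, 3])) coords <- unname(xyz)
  }
  # ChemmineR represents a bond-less record as a zero-filled stub row
  bonds <- NULL
  if (!is.null(bb) && length(bb) >= 3L) {
    bm <- if (is.null(dim(bb))) matrix(bb[1:3], nrow = 1) else
      bb[, 1:3, drop = FALSE]
    bm <- bm[bm[, 1] > 0 & bm[, 2] > 0, , drop = FALSE]
    if (nrow(bm)) {
      bonds <- data.frame(i = bm[, 1], j = bm[, 2], order = bm[, 3])
    }
  }
  nm <- name %||% ChemmineR::sdfid(sdf)
  if (is.null(nm) || !nzchar(nm)) nm <- "mol"
  mol_graph(data.frame(element = element, charge = charge),
            bonds, coords = coords, name = nm)
}

# Minimal fixed-width V2000 fallback for records ChemmineR cannot represent
# (molecules without bonds). Standard column layout only.
parse_v2000_text <- function(sdf_text, name = NULL, keep_coords = TRUE) {
  lines <- strsplit(paste(sdf_text, collapse = "\n"), "\n")[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) abort_input("malformed V2000 counts line")
  at <- lines[4 + seq_len(na)]
  atoms <- data.frame(
    element = trimws(substr(at, 32, 34)),
    charge = 0L)
  xyz <- cbind(as.numeric(substr(at, 1, 10)),
               as.numeric(substr(at, 11, 20)),
               as.numeric(substr(at, 21, 30)))
  bonds <- NULL
  if (!is.na(nb) && nb > 0L) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = as.integer(substr(bl, 7, 9)))
  }
  chg <- sdf_charges(sdf_text)
  if (nrow(chg)) atoms$charge[chg$atom] <- chg$charge
  coords <- NULL
  if (keep_coords && sdf_is_3d(sdf_text, xyz[, 3])) coords <- xyz
  mol_graph(atoms, bonds, coords = coords,
            name = name %||% trimws(lines[1]))
}

# A record counts as 3D when its header line carries the 3D dimension flag
# or any z coordinate is non-zero (planar 3D structures keep the flag).
sdf_is_3d <- function(raw_text, z) {
  if (any(abs(z) > 1e-8)) return(TRUE)
  if (is.null(raw_text)) return(FALSE)
  lines <- strsplit(paste(raw_text, collapse = "\n"), "\n")[[1]]
  length(lines) >= 2L && grepl("3D", lines[2], fixed = TRUE)
}

# Formal charges from the `M  CHG` property lines of a single V2000 record.
sdf_charges <- function(sdf_text) {
  lines <- strsplit(paste(sdf_text, collapse = "\n"), "\n")[[1]]
  lines <- lines[startsWith(lines, "M  CHG")]
  out <- data.frame(atom = integer(), charge = integer())
  for (ln in lines) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    k <- f[1]
    for (e in seq_len(k)) {
      out <- rbind(out, data.frame(atom = f[2 * e], charge = f[2 * e + 1]))
    }
  }
  out
}

#' Read molecules from SMILES
#'
#' `read_smiles()` parses a single SMILES string; `read_smiles_file()` reads a
#' SMILES file with one record per line (`SMILES[ whitespace NAME]`), skipping
#' blank lines and `#` comments. Parsing, sanitisation and kekulisation are
#' delegated to OpenBabel.
#'
#' @param smiles a SMILES string.
#' @param name molecule name.
#' @param path path to a SMILES file.
#' @return a `mol_graph` (`read_smiles`) or list of `mol_graph`
#'   (`read_smiles_file`). Hydrogens stay implicit at this stage.
#' @export
read_smiles <- function(smiles, name = "mol") {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles))) {
    abort_input("'smiles' must be a single non-empty string")
  }
  sdf <- ob_convert("SMI", "SDF", paste0(trimws(smiles), " ", name, "\n"))
  sdf_text_to_mol(sdf, name = name, keep_coords = FALSE)
}

#' @rdname read_smiles
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) abort_input("SMILES file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort_input("no molecule records in ", path)
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\\s+")[[1]]
    nm <- if (length(f) >= 2) paste(f[-1], collapse = " ") else paste0("mol", k)
    out[[k]] <- tryCatch(read_smiles(f[1], name = nm), error = function(e) {
      abort_input("record ", k, " ('", nm, "') of ", path, ": ",
                  conditionMessage(e))
    })
  }
  out
}

#' Read molecules from an SDF/MOL V2000 file
#'
#' @param path path to an SDF or MOL file.
#' @return list of `mol_graph` objects (coordinates kept when 3D).
#' @export
read_sdf_file <- function(path) {
  if (!file.exists(path)) abort_input("SDF file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  recs <- split(raw, cumsum(c(0, head(raw == "$$$$", -1))))
  out <- list()
  for (r in recs) {
    txt <- paste(r, collapse = "\n")
    if (!grepl("V2000", txt)) next
    out[[length(out) + 1L]] <- sdf_text_to_mol(txt)
  }
  if (!length(out)) abort_input("no V2000 molecule records in ", path)
  out
}

#' Write a molecule (or fragment) as an SDF V2000 record
#'
#' Cap hydrogens of fragments are flagged in a `> <cap_atoms>` data field
#' (1-based atom indices).
#'
#' @param mol a `mol_graph` or `mol_fragment`.
#' @param path optional output file; when `NULL` the SDF text is returned.
#' @return the SDF text, invisibly when written to a file.
#' @export
write_sdf <- function(mol, path = NULL) {
  frag <- NULL
  if (inherits(mol, "mol_fragment")) {
    frag <- mol
    mol <- mol$graph
  }
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  xyz <- mol$coords %||% matrix(0, n, 3)
  dim_tag <- if (is.null(mol$coords)) "2D" else "3D"
  lines <- c(
    mol$name,
    sprintf("  atroposcan        %s", dim_tag),
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element),
    if (nb) sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                    as.integer(mol$bonds$order))
  )
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg,
                                            mol$atoms$charge[chg]),
                                    collapse = "")))
  }
  lines <- c(lines, "M  END")
  if (!is.null(frag) && length(frag$cap_atoms)) {
    lines <- c(lines, "> <cap_atoms>",
               paste(frag$cap_atoms, collapse = " "), "")
  }
  lines <- c(lines, "$$$$")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Molecular formula (Hill order, implicit hydrogens included)
#'
#' Hydrogen counts are completed by the OpenBabel valence model, so graphs
#' read from SMILES (no explicit hydrogens) report their full formula.
#'
#' @param mol a `mol_graph`.
#' @return formula string, e.g. `"C40H49BrN6O9S"`.
#' @export
molecular_formula <- function(mol) {
  sdf_h <- ob_convert("SDF", "SDF", write_sdf(mol), add_h = TRUE)
  m <- sdf_text_to_mol(sdf_h, name = mol$name, keep_coords = FALSE)
  tab <- table(m$atoms$element)
  els <- names(tab)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    k <- tab[[e]]
    paste0(e, if (k > 1L) k else "")
  }, character(1)), collapse = "")
}
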