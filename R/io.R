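#' Read a per-atom parameter table
#'
#' Force-field assignment is out of scope for this package, so partial
#' charges, Lennard-Jones parameters, Born radii and masses are explicit
#' inputs supplied as a tab-separated sidecar table with columns
#' `atom_name`, `charge`, `sigma`, `epsilon`, `born_radius`, `mass`.
#' A row whose `atom_name` is `*X` acts as a wildcard fallback for every
#' atom of element `X` that has no exact-name row.
#'
#' @param path Path to the TSV file (LF or CRLF line endings).
#' @return A `param_table` object usable by [read_pdb()].
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("atom_name", "charge", "sigma", "epsilon", "born_radius", "mass")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("parameter table lacks columns: ", paste(missing_cols, collapse = ", "))
  structure(tab, class = c("param_table", "data.frame"))
}

#' In-memory parameter table
#'
#' @param atom_name,charge,sigma,epsilon,born_radius,mass Parallel vectors;
#'   `atom_name` entries of the form `*X` are element wildcards.
#' @return A `param_table`.
#' @export
param_table <- function(atom_name, charge, sigma, epsilon, born_radius, mass) {
  structure(data.frame(atom_name = atom_name, charge = charge, sigma = sigma,
                       epsilon = epsilon, born_radius = born_radius,
                       mass = mass, stringsAsFactors = FALSE),
            class = c("param_table", "data.frame"))
}

lookup_params <- function(params, atom_names, elements) {
  idx <- match(atom_names, params$atom_name)
  wild <- is.na(idx)
  if (any(wild)) {
    idx[wild] <- match(paste0("*", toupper(elements[wild])), params$atom_name)
    if (anyNA(idx))
      stop("parameterization error: no parameters for atom(s) ",
           paste(unique(atom_names[is.na(idx)]), collapse = ", "))
  }
  params[idx, c("charge", "sigma", "epsilon", "born_radius", "mass")]
}

guess_element <- function(name) {
  # PDB atom names put the element in the leading letters; strip digits
  e <- sub("^[0-9]*", "", trimws(name))
  two <- toupper(substr(e, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA"),
         two, toupper(substr(e, 1, 1)))
}

#' Read a PDB file into a molecular_structure
#'
#' ATOM/HETATM records are parsed with `bio3d::read.pdb()`; CONECT records
#' become harmonic bonds with the observed inter-atomic distance as the
#' equilibrium length.  Per-atom energetic parameters come from the
#' sidecar table (see [read_param_table()]).
#'
#' @param path Path to the PDB file.
#' @param params A `param_table`.
#' @param role `"receptor"` or `"ligand"`.
#' @param label Structure label; defaults to the file stem.
#' @param bond_k Force constant assigned to CONECT-derived bonds
#'   (kcal mol^-1 A^-2).
#' @return A `molecular_structure` with atom order preserved from the file.
#' @export
read_pdb <- function(path, params, role = c("receptor", "ligand"),
                     label = NULL, bond_k = 300) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("format error reading '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  element <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                    trimws(at$elesy), guess_element(at$elety))
  pp <- lookup_params(params, trimws(at$elety), element)
  atoms <- data.frame(name = trimws(at$elety), element = element,
                      x = at$x, y = at$y, z = at$z,
                      charge = pp$charge, sigma = pp$sigma,
                      epsilon = pp$epsilon, born_radius = pp$born_radius,
                      mass = pp$mass,
                      resno = at$resno, resid = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      stringsAsFactors = FALSE)
  bonds <- parse_conect(path, at$eleno, bond_k,
                        as.matrix(atoms[, c("x", "y", "z")]))
  molecular_structure(atoms, bonds, role = role, label = label)
}

parse_conect <- function(path, serials, bond_k, xyz) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  con <- lines[startsWith(lines, "CONECT")]
  if (!length(con))
    return(data.frame(i = integer(), j = integer(), kb = numeric(), b0 = numeric()))
  pairs <- do.call(rbind, lapply(con, function(l) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substring(l, 7)), "\\s+")[[1]]))
    if (anyNA(f) || length(f) < 2)
      stop("format error: unparseable CONECT record: '", l, "'")
    cbind(f[1], f[-1])
  }))
  i <- match(pairs[, 1], serials); j <- match(pairs[, 2], serials)
  if (anyNA(i) || anyNA(j))
    stop("format error: CONECT references unknown atom serial")
  # dedupe symmetric duplicates
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(paste(lo, hi)) & lo != hi
  lo <- lo[keep]; hi <- hi[keep]
  b0 <- sqrt(rowSums((xyz[lo, , drop = FALSE] - xyz[hi, , drop = FALSE])^2))
  data.frame(i = lo, j = hi, kb = bond_k, b0 = b0)
}

#' Write a molecular_structure to a PDB file
#'
#' Emits standard fixed-width ATOM (receptor) or HETATM (ligand) records
#' with 3-decimal coordinates, the structure's CONECT records, and END.
#' Output is deterministic.
#'
#' @param structure A `molecular_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "molecular_structure"))
  at <- structure$atoms
  n <- nrow(at)
  type <- rep(if (structure$role == "ligand") "HETATM" else "ATOM", n)
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(structure))),
                     type = type, resno = at$resno, resid = at$resid,
                     eleno = seq_len(n), elety = at$name, chain = at$chain,
                     elesy = at$element, end = FALSE)
    TRUE
  }, error = function(e) stop("I/O error writing '", path, "': ",
                              conditionMessage(e)))
  con <- file(path, open = "a")
  on.exit(close(con))
  if (nrow(structure$bonds))
    writeLines(sprintf("CONECT%5d%5d", structure$bonds$i, structure$bonds$j), con)
  writeLines("END   ", con)
  invisible(path)
}

#' Write a complex (receptor + ligand) as a single PDB file
#'
#' @param system A `complex_system`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_complex_pdb <- function(system, path) {
  stopifnot(inherits(system, "complex_system"))
  rec <- system$receptor; lig <- system$ligand
  n_r <- nrow(rec$atoms); n_l <- nrow(lig$atoms)
  at <- rbind(rec$atoms[, c("name", "element", "resno", "resid", "chain")],
              lig$atoms[, c("name", "element", "resno", "resid", "chain")])
  xyz <- rbind(coords(rec), coords(lig))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = c(rep("ATOM", n_r), rep("HETATM", n_l)),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(n_r + n_l), elety = at$name,
                   chain = at$chain, elesy = at$element, end = FALSE)
  con <- file(path, open = "a")
  on.exit(close(con))
  if (nrow(lig$bonds))
    writeLines(sprintf("CONECT%5d%5d", lig$bonds$i + n_r, lig$bonds$j + n_r), con)
  writeLines("END   ", con)
  invisible(path)
}
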