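#' Molecular structure container
#'
#' A lightweight container for one cluster geometry: element symbols,
#' Cartesian coordinates in Angstrom, an optional electronic energy in
#' hartree, and a phase tag distinguishing gas-phase species from species
#' embedded in a dielectric continuum ("solvent").
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param label character identifier, e.g. `"IMZW3_1"`.
#' @param energy electronic energy in hartree, or `NA` when not available.
#' @param phase `"gas"` or `"solvent"`.
#' @return An object of class `"xyz_structure"`.
#' @export
structure_xyz <- function(elements, coords, label = "", energy = NA_real_,
                          phase = c("gas", "solvent")) {
  phase <- match.arg(phase)
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix")
  if (length(elements) != nrow(coords))
    stop("length(elements) must equal nrow(coords)")
  if (!is.na(energy) && !is.finite(energy))
    stop("energy must be finite or NA")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  obj <- list(label = as.character(label),
              elements = as.character(elements),
              coords = coords,
              energy = as.numeric(energy),
              phase = phase)
  class(obj) <- "xyz_structure"
  obj
}

#' @export
print.xyz_structure <- function(x, ...) {
  comp <- table(x$elements)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat(sprintf("<xyz_structure> %s: %d atoms (%s), phase=%s",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$elements), formula, x$phase))
  if (!is.na(x$energy)) cat(sprintf(", E = %.6f hartree", x$energy))
  cat("\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s an `xyz_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) length(s$elements)

#' Read a (multi-record) XYZ file
#'
#' Standard XYZ: per record an atom count line, a comment line, then one
#' `element x y z` line per atom. The comment line may carry `key=value`
#' tokens; `label=`, `energy=` (hartree) and `phase=` (`gas`/`solvent`) are
#' recognised, unknown tokens are ignored. A bare first token that is not
#' `key=value` is taken as the label.
#'
#' @param path path to an XYZ file.
#' @return list of [structure_xyz()] objects (possibly empty).
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  # drop trailing blank lines only; internal blanks are comment lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0L)
      stop(sprintf("record %d, line %d: malformed atom count '%s'",
                   rec, i, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("record %d: truncated (expected %d atoms)", rec, nat))
    comment <- if (nat >= 0L && i + 1L <= length(lines)) lines[i + 1L] else ""
    meta <- .parse_xyz_comment(comment)
    elements <- character(nat)
    coords <- matrix(0, nat, 3L)
    for (k in seq_len(nat)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("record %d, line %d: expected 'element x y z'", rec, ln))
      el <- tok[1]
      if (!el %in% names(.covalent_radii))
        stop(sprintf("record %d, line %d: unknown element symbol '%s'",
                     rec, ln, el))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop(sprintf("record %d, line %d: non-numeric coordinate", rec, ln))
      elements[k] <- el
      coords[k, ] <- xyz
    }
    out[[rec]] <- structure_xyz(elements, coords,
                                label = meta$label, energy = meta$energy,
                                phase = meta$phase)
    i <- i + 2L + nat
  }
  out
}

.parse_xyz_comment <- function(comment) {
  meta <- list(label = "", energy = NA_real_, phase = "gas")
  tok <- strsplit(trimws(comment), "[[:space:]]+")[[1]]
  tok <- tok[nzchar(tok)]
  for (j in seq_along(tok)) {
    kv <- regmatches(tok[j], regexec("^([A-Za-z_]+)=(.*)$", tok[j]))[[1]]
    if (length(kv) == 3L) {
      key <- kv[2]; val <- kv[3]
      if (key == "label") meta$label <- val
      else if (key == "energy") {
        e <- suppressWarnings(as.numeric(val))
        if (is.na(e)) stop("non-numeric energy in comment line: ", tok[j])
        meta$energy <- e
      } else if (key == "phase") {
        if (!val %in% c("gas", "solvent"))
          stop("unknown phase tag '", val, "' (expected gas or solvent)")
        meta$phase <- val
      } # unknown key=value tokens ignored
    } else if (j == 1L) {
      meta$label <- tok[j]
    }
  }
  meta
}

#' Write structures to a multi-record XYZ file
#'
#' Inverse of [read_xyz()]: label, energy and phase are encoded as
#' `key=value` tokens on the comment line, coordinates with enough digits
#' that a read/write round trip preserves them to better than 1e-6 Angstrom.
#'
#' @param structures a list of `xyz_structure` objects (a single structure
#'   is accepted and wrapped).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structures, path) {
  if (inherits(structures, "xyz_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    meta <- character(0)
    if (nzchar(s$label)) meta <- c(meta, paste0("label=", s$label))
    if (!is.na(s$energy))
      meta <- c(meta, sprintf("energy=%.12f", s$energy))
    meta <- c(meta, paste0("phase=", s$phase))
    writeLines(c(as.character(n_atoms(s)), paste(meta, collapse = " ")), con)
    for (k in seq_len(n_atoms(s))) {
      writeLines(sprintf("%-2s %16.10f %16.10f %16.10f", s$elements[k],
                         s$coords[k, 1], s$coords[k, 2], s$coords[k, 3]), con)
    }
  }
  invisible(path)
}

#' Perceive molecular fragments from interatomic distances
#'
#' Two atoms are bonded when their distance is below `scale` times the sum
#' of their covalent radii; fragments are the connected components of the
#' resulting bond graph. Deterministic: fragment ids are assigned in order
#' of each fragment's lowest atom index, starting at 1.
#'
#' @param s an `xyz_structure`.
#' @param scale bond-detection cutoff multiplier (default 1.2, robust for
#'   H/C/N/O organic clusters).
#' @return An object of class `"fragment_assignment"`: list with
#'   `fragment_ids` (integer per atom), `formulas` (Hill-ordered formula per
#'   fragment), `imidazole_fragment` (id or `NA`), `water_fragments`
#'   (integer ids), and the `bonds` adjacency list used.
#' @export
perceive_fragments <- function(s, scale = 1.2) {
  stopifnot(inherits(s, "xyz_structure"), scale > 0)
  n <- n_atoms(s)
  radii <- .covalent_radii[s$elements]
  d <- as.matrix(stats::dist(s$coords))
  cutoff <- outer(radii, radii, "+") * scale
  adj <- d < cutoff
  diag(adj) <- FALSE
  # connected components by BFS
  ids <- integer(n)
  next_id <- 0L
  for (start in seq_len(n)) {
    if (ids[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    ids[start] <- next_id
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nb <- which(adj[a, ] & ids == 0L)
      ids[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  formulas <- vapply(seq_len(next_id), function(fid) {
    .hill_formula(s$elements[ids == fid])
  }, character(1))
  imz <- which(formulas == "C3H4N2")
  obj <- list(fragment_ids = ids,
              formulas = formulas,
              imidazole_fragment = if (length(imz) == 1L) imz else NA_integer_,
              water_fragments = which(formulas == "H2O"),
              adjacency = adj)
  class(obj) <- "fragment_assignment"
  obj
}

.hill_formula <- function(elements) {
  comp <- table(elements)
  ord <- names(comp)
  # Hill order: C first, H second, rest alphabetical
  ord <- c(intersect(c("C", "H"), ord), sort(setdiff(ord, c("C", "H"))))
  paste0(ord, ifelse(comp[ord] > 1, comp[ord], ""), collapse = "")
}

#' @export
print.fragment_assignment <- function(x, ...) {
  cat(sprintf("<fragment_assignment> %d fragment(s): %s\n",
              length(x$formulas), paste(x$formulas, collapse = " + ")))
  invisible(x)
}

#' Number of water molecules in a cluster
#'
#' @param s an `xyz_structure`.
#' @param f optional precomputed [perceive_fragments()] result.
#' @return integer count of H2O fragments.
#' @export
count_waters <- function(s, f = perceive_fragments(s)) {
  length(f$water_fragments)
}

#' Label the imidazole ring atoms by chemical role
#'
#' Identifies, within the imidazole fragment, the pyrrole-type nitrogen N1
#' (ring N bearing a hydrogen, the H-bond donor site), the pyridine-type
#' nitrogen N3 (no hydrogen, the acceptor site), the carbons C2 (between
#' the nitrogens), C4 (adjacent to N3) and C5 (adjacent to N1), the N1
#' hydrogen, and the unit normal of the best-fit ring plane.
#'
#' @param s an `xyz_structure` containing an imidazole fragment.
#' @param f a [perceive_fragments()] result for `s`.
#' @return An object of class `"imidazole_roles"`: list with atom indices
#'   `N1`, `N3`, `C2`, `C4`, `C5`, `H_N1`, the ring index vector `ring`,
#'   `centroid` and `normal` of the ring plane.
#' @export
label_imidazole <- function(s, f = perceive_fragments(s)) {
  if (is.na(f$imidazole_fragment))
    stop("no imidazole (C3H4N2) fragment in structure")
  atoms <- which(f$fragment_ids == f$imidazole_fragment)
  el <- s$elements
  adj <- f$adjacency
  ringN <- atoms[el[atoms] == "N"]
  ringC <- atoms[el[atoms] == "C"]
  has_h <- vapply(ringN, function(a) sum(adj[a, ] & el == "H"), integer(1))
  if (sum(has_h == 1L) != 1L || sum(has_h == 0L) != 1L)
    stop("cannot assign N1/N3 roles: expected exactly one H-bearing ring ",
         "nitrogen (found ", sum(has_h >= 1L), "); protonated or ",
         "deprotonated ring?")
  N1 <- ringN[has_h == 1L]
  N3 <- ringN[has_h == 0L]
  H_N1 <- which(adj[N1, ] & el == "H")[1]
  C2 <- ringC[adj[ringC, N1] & adj[ringC, N3]]
  C5 <- ringC[adj[ringC, N1] & !adj[ringC, N3]]
  C4 <- ringC[adj[ringC, N3] & !adj[ringC, N1]]
  if (length(C2) != 1L || length(C4) != 1L || length(C5) != 1L)
    stop("imidazole ring connectivity is not the expected 5-cycle")
  ring <- c(N1, C2, N3, C4, C5)
  centroid <- colMeans(s$coords[ring, , drop = FALSE])
  sv <- svd(sweep(s$coords[ring, , drop = FALSE], 2, centroid))
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  obj <- list(N1 = N1, N3 = N3, C2 = C2, C4 = C4, C5 = C5, H_N1 = H_N1,
              ring = ring, centroid = centroid, normal = normal)
  class(obj) <- "imidazole_roles"
  obj
}

#' @export
print.imidazole_roles <- function(x, ...) {
  cat(sprintf(
    "<imidazole_roles> N1=%d (H=%d) N3=%d C2=%d C4=%d C5=%d\n",
    x$N1, x$H_N1, x$N3, x$C2, x$C4, x$C5))
  invisible(x)
}
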