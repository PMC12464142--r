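# Geometric detection of non-covalent contacts. Electron-density (QTAIM)
# classification needs SCF densities; the same four imidazole-water
# interaction classes (OH...N3, N1H...O, CH...O, OH...pi) plus water-water
# OH...O are recovered here from distance and angle criteria alone.

#' Geometric hydrogen-bond criteria
#'
#' A donor-H...acceptor triple counts as a contact when the H...acceptor
#' distance is below the cutoff and the D-H...A angle is at least
#' `angle_min`. Conventional crystallographic values are the defaults:
#' 2.6 Angstrom for O/N acceptors, 3.0 Angstrom for the ring-centroid
#' (pi) acceptor, 120 degrees.
#'
#' @param d_ha_max H...acceptor cutoff for O/N acceptors, Angstrom.
#' @param d_ha_pi_max H...ring-centroid cutoff, Angstrom.
#' @param angle_min minimum D-H...A angle, degrees, in (0, 180].
#' @param pi_centroid include the imidazole ring centroid as an acceptor.
#' @return object of class `"contact_criteria"`.
#' @export
contact_criteria <- function(d_ha_max = 2.6, d_ha_pi_max = 3.0,
                             angle_min = 120, pi_centroid = TRUE) {
  stopifnot(d_ha_max > 0, d_ha_pi_max > 0,
            angle_min > 0, angle_min <= 180)
  obj <- list(d_ha_max = d_ha_max, d_ha_pi_max = d_ha_pi_max,
              angle_min = angle_min, pi_centroid = isTRUE(pi_centroid))
  class(obj) <- "contact_criteria"
  obj
}

.angle_deg <- function(a, b, c) {
  # angle at b of the triple a-b-c
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Detect inter-fragment non-covalent contacts
#'
#' Enumerates all donor-H...acceptor triples across distinct fragments
#' that satisfy the geometric criteria. Donors are O-H, N-H and C-H
#' groups; acceptors are O and N atoms of other fragments and, when roles
#' are supplied, the imidazole ring centroid (pi acceptor). Contacts are
#' typed by the chemistry of the pair: `OH...N3`, `N1H...O`, `CH...O`,
#' `OH...pi`, water-water `OH...O`, or `other`.
#'
#' @param s an `xyz_structure`.
#' @param f a [perceive_fragments()] result for `s`.
#' @param roles an [label_imidazole()] result, or `NULL` for structures
#'   without imidazole (then only generic typing is possible).
#' @param criteria a [contact_criteria()].
#' @return object of class `"contact_report"`: list with `contacts` (a
#'   data.frame: donor, h, acceptor (`NA` for the centroid), type, d_ha,
#'   angle, out_of_plane), and `census` (named counts of `N3_accepted`,
#'   `N1H_donated`, `CH_O`, `OH_pi`, `water_water`).
#' @export
detect_contacts <- function(s, f = perceive_fragments(s),
                            roles = if (!is.na(f$imidazole_fragment))
                              label_imidazole(s, f) else NULL,
                            criteria = contact_criteria()) {
  stopifnot(inherits(s, "xyz_structure"), inherits(f, "fragment_assignment"))
  el <- s$elements
  xyz <- s$coords
  ids <- f$fragment_ids
  hs <- which(el == "H")
  rows <- list()
  for (h in hs) {
    donors <- which(f$adjacency[h, ] & el %in% c("O", "N", "C"))
    if (!length(donors)) next
    d_atom <- donors[1]
    # O/N acceptors on other fragments
    acceptors <- which(el %in% c("O", "N") & ids != ids[h])
    for (a in acceptors) {
      d_ha <- sqrt(sum((xyz[h, ] - xyz[a, ])^2))
      if (d_ha > criteria$d_ha_max) next
      ang <- .angle_deg(xyz[d_atom, ], xyz[h, ], xyz[a, ])
      if (ang < criteria$angle_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d_atom, h = h, acceptor = a,
        type = .contact_type(el, ids, f, roles, d_atom, h, a),
        d_ha = d_ha, angle = ang,
        out_of_plane = NA_real_)
    }
    # ring-centroid (pi) acceptor
    if (!is.null(roles) && criteria$pi_centroid &&
        ids[h] != ids[roles$N1] && el[d_atom] == "O") {
      d_ha <- sqrt(sum((xyz[h, ] - roles$centroid)^2))
      if (d_ha <= criteria$d_ha_pi_max) {
        ang <- .angle_deg(xyz[d_atom, ], xyz[h, ], roles$centroid)
        if (ang >= criteria$angle_min) {
          rows[[length(rows) + 1L]] <- data.frame(
            donor = d_atom, h = h, acceptor = NA_integer_,
            type = "OH...pi", d_ha = d_ha, angle = ang,
            out_of_plane = NA_real_)
        }
      }
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = integer(0), h = integer(0), acceptor = integer(0),
               type = character(0), d_ha = numeric(0), angle = numeric(0),
               out_of_plane = numeric(0))
  if (!is.null(roles) && nrow(contacts)) {
    to_n3 <- which(!is.na(contacts$acceptor) &
                     contacts$acceptor == roles$N3)
    for (i in to_n3)
      contacts$out_of_plane[i] <-
        out_of_plane_angle(s, roles, contacts$donor[i])
  }
  census <- c(
    N3_accepted = if (is.null(roles)) 0L else
      sum(!is.na(contacts$acceptor) & contacts$acceptor == roles$N3),
    N1H_donated = sum(contacts$type == "N1H...O"),
    CH_O = sum(contacts$type == "CH...O"),
    OH_pi = sum(contacts$type == "OH...pi"),
    water_water = sum(contacts$type == "OH...O"))
  obj <- list(contacts = contacts, census = census,
              label = s$label, criteria = criteria)
  class(obj) <- "contact_report"
  obj
}

.contact_type <- function(el, ids, f, roles, d_atom, h, a) {
  if (!is.null(roles)) {
    if (a == roles$N3 && el[d_atom] == "O") return("OH...N3")
    if (d_atom == roles$N1 && el[a] == "O") return("N1H...O")
    if (el[d_atom] == "C" && ids[d_atom] == ids[roles$N1] &&
        el[a] == "O") return("CH...O")
  }
  wat <- f$water_fragments
  if (el[d_atom] == "O" && el[a] == "O" &&
      ids[d_atom] %in% wat && ids[a] %in% wat) return("OH...O")
  "other"
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("<contact_report> %s: %d contact(s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$contacts)))
  if (nrow(x$contacts)) {
    tab <- table(x$contacts$type)
    cat("  ", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  census: N3_accepted=%d N1H_donated=%d CH_O=%d OH_pi=%d water_water=%d\n",
              x$census["N3_accepted"], x$census["N1H_donated"],
              x$census["CH_O"], x$census["OH_pi"],
              x$census["water_water"]))
  invisible(x)
}

#' Out-of-plane angle of an N3-bound donor
#'
#' Angle between the N3 -> donor-atom vector and the imidazole ring plane,
#' in degrees: 0 for an in-plane donor, 90 for one along the plane normal.
#'
#' @param s the `xyz_structure`.
#' @param roles an [label_imidazole()] result for `s`.
#' @param atom index of the donor heavy atom (typically a water oxygen),
#'   or a length-3 position vector.
#' @return angle in degrees, in [0, 90].
#' @export
out_of_plane_angle <- function(s, roles, atom) {
  pos <- if (length(atom) == 3L && is.numeric(atom) && !is.integer(atom))
    atom else s$coords[atom, ]
  v <- pos - s$coords[roles$N3, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("donor coincides with N3")
  asin(max(-1, min(1, abs(sum(v * roles$normal)) / nv))) * 180 / pi
}

#' Aggregate hydrogen-bond census over an ensemble
#'
#' @param reports list of [detect_contacts()] results.
#' @return object of class `"census_summary"`: list with `counts` (a
#'   members x classes matrix) and `modal` (the modal count per class;
#'   ties resolved toward the smaller count).
#' @export
census_summary <- function(reports) {
  if (!length(reports)) stop("no contact reports supplied")
  counts <- do.call(rbind, lapply(reports, function(r) r$census))
  modal <- apply(counts, 2, function(v) {
    tab <- table(v)
    as.numeric(names(tab)[which.max(tab)])
  })
  obj <- list(counts = counts, modal = modal)
  class(obj) <- "census_summary"
  obj
}

#' @export
print.census_summary <- function(x, ...) {
  cat(sprintf("<census_summary> %d member(s); modal counts:\n",
              nrow(x$counts)))
  print(x$modal)
  invisible(x)
}
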