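#' Arterial network objects
#'
#' A vessel network is a rooted directed binary tree of straight vessel
#' segments. Each vessel has an integer \code{id}, a \code{parent_id}
#' (\code{NA} for the root), a length (cm), an unstressed radius (cm) and a
#' terminal flag. Internal vessels have exactly two daughters; terminal
#' vessels carry a three-element Windkessel outflow model.
#'
#' @param vessels a data frame with columns \code{id}, \code{parent_id},
#'   \code{length_cm}, \code{r0_cm}, \code{terminal}. \code{parent_id} is
#'   \code{NA} (or empty) for the root.
#' @return An object of class \code{"vessel_network"}: a list with the
#'   validated \code{vessels} table (ordered by id, with unstressed area
#'   \code{A0_cm2} added) and a \code{junctions} matrix of
#'   (parent, daughter1, daughter2) id triples, daughters ordered by id.
#' @examples
#' vessel_network(data.frame(
#'   id = 1:3, parent_id = c(NA, 1, 1),
#'   length_cm = c(0.4, 0.3, 0.3), r0_cm = c(0.05, 0.04, 0.04),
#'   terminal = c(FALSE, TRUE, TRUE)))
#' @export
vessel_network <- function(vessels) {
  need <- c("id", "parent_id", "length_cm", "r0_cm", "terminal")
  miss <- setdiff(need, names(vessels))
  if (length(miss))
    stop("vessel table is missing column(s): ", paste(miss, collapse = ", "))
  v <- vessels[need]
  v$id <- as.integer(v$id)
  v$parent_id <- suppressWarnings(as.integer(v$parent_id))
  v$terminal <- as.logical(v$terminal)
  if (anyDuplicated(v$id)) stop("duplicate vessel ids")
  if (any(!is.finite(v$length_cm)) || any(v$length_cm <= 0))
    stop("vessel lengths must be positive")
  if (any(!is.finite(v$r0_cm)) || any(v$r0_cm <= 0))
    stop("vessel radii must be positive")
  v <- v[order(v$id), , drop = FALSE]
  rownames(v) <- NULL

  root <- v$id[is.na(v$parent_id)]
  if (length(root) != 1L)
    stop("network must have exactly one root (found ", length(root), ")")
  known <- v$parent_id[!is.na(v$parent_id)]
  bad <- setdiff(known, v$id)
  if (length(bad))
    stop("vessel lists nonexistent parent id: ", paste(bad, collapse = ", "))

  ## children per vessel
  kids <- split(v$id[!is.na(v$parent_id)], factor(known, levels = v$id))
  n_kids <- vapply(kids, length, 1L)
  if (any(n_kids == 1L))
    stop("vessel(s) with exactly one daughter: ",
         paste(v$id[n_kids == 1L], collapse = ", "))
  if (any(n_kids > 2L))
    stop("vessel(s) with more than two daughters: ",
         paste(v$id[n_kids > 2L], collapse = ", "))
  term_mismatch <- v$id[(n_kids == 0L) != v$terminal]
  if (length(term_mismatch))
    stop("terminal flag inconsistent with topology for vessel(s): ",
         paste(term_mismatch, collapse = ", "))

  ## cycle / reachability check: walk up from every vessel
  parent_of <- stats::setNames(v$parent_id, v$id)
  for (id in v$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(parent_of[[as.character(cur)]])) {
      cur <- parent_of[[as.character(cur)]]
      if (cur %in% seen || length(seen) > nrow(v))
        stop("cycle detected involving vessel ", id)
      seen <- c(seen, cur)
    }
    if (cur != root) stop("vessel ", id, " is not connected to the root")
  }

  v$A0_cm2 <- pi * v$r0_cm^2
  internal <- v$id[n_kids == 2L]
  junctions <- if (length(internal)) {
    t(vapply(internal,
             function(p) c(p, sort(kids[[as.character(p)]])), integer(3)))
  } else {
    matrix(integer(0), 0, 3)
  }
  colnames(junctions) <- c("parent", "d1", "d2")
  structure(list(vessels = v, junctions = junctions, root = root),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  v <- x$vessels
  cat("Vessel network:", nrow(v), "vessels,", sum(v$terminal),
      "terminal,", nrow(x$junctions), "junctions (root id ", x$root, ")\n",
      sep = " ")
  cat(sprintf("  radius range %.4f-%.4f cm, total length %.3f cm\n",
              min(v$r0_cm), max(v$r0_cm), sum(v$length_cm)))
  invisible(x)
}

#' Read a vessel network from CSV or JSON
#'
#' The CSV schema is \code{id,parent_id,length_cm,r0_cm,terminal} with an
#' empty \code{parent_id} for the root; the JSON form is an array of objects
#' with the same fields (parent_id \code{null} for the root).
#'
#' @param path file path; format inferred from the \code{.json} extension,
#'   CSV otherwise.
#' @return a validated \code{\link{vessel_network}}.
#' @examples
#' ## synthetic 21-vessel mouse tree shipped with the package
#' net <- read_network(system.file("extdata",
#'   "mouse_network_synthetic_21.csv", package = "pulmouq"))
#' sum(net$vessels$terminal)  # 11
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("id", "parent_id", "length_cm", "r0_cm", "terminal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed network file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if ("parent_id" %in% names(df) && is.character(df$parent_id))
    df$parent_id[df$parent_id == ""] <- NA
  vessel_network(df)
}

#' Write a vessel network to CSV or JSON
#'
#' @param network a \code{\link{vessel_network}}.
#' @param path output path; \code{.json} selects JSON, CSV otherwise.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path) {
  v <- network$vessels[c("id", "parent_id", "length_cm", "r0_cm", "terminal")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(v, path, dataframe = "rows", na = "null",
                         digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(v, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Generate a synthetic binary arterial tree
#'
#' Stand-in geometry for an imaged pulmonary network: a binary tree with
#' \code{n_terminal} leaves in which daughter radii shrink by
#' \code{radius_ratio} per generation, with a small seeded left/right
#' asymmetry so the two lungs receive unequal flow, and lengths proportional
#' to the radius.
#'
#' @param n_terminal number of terminal vessels (>= 2).
#' @param root_radius unstressed radius of the root vessel, cm.
#' @param radius_ratio per-generation daughter/parent radius factor, in
#'   (0, 1].
#' @param length_radius_ratio vessel length / radius (dimensionless).
#' @param asymmetry relative radius perturbation between sibling daughters.
#' @param seed integer seed; the same seed reproduces the same tree.
#' @return a \code{\link{vessel_network}} with \code{2 * n_terminal - 1}
#'   vessels.
#' @examples
#' net <- generate_tree(n_terminal = 11, seed = 1)
#' nrow(net$vessels)  # 21
#' @export
generate_tree <- function(n_terminal, root_radius = 0.047,
                          radius_ratio = 0.82, length_radius_ratio = 9,
                          asymmetry = 0.06, seed = 1) {
  if (n_terminal < 2) stop("n_terminal must be at least 2")
  if (radius_ratio <= 0 || radius_ratio > 1)
    stop("radius_ratio must lie in (0, 1]")
  if (length_radius_ratio <= 0) stop("length_radius_ratio must be positive")
  rng <- local({ set.seed(seed); function(n) stats::runif(n) })

  ## grow by repeatedly splitting the widest current leaf
  id <- 1L
  rows <- list(list(id = 1L, parent_id = NA_integer_, r0 = root_radius))
  leaves <- 1L
  r_of <- c("1" = root_radius)
  while (length(leaves) < n_terminal) {
    split_leaf <- leaves[which.max(r_of[as.character(leaves)])]
    eps <- asymmetry * (2 * rng(1) - 1)
    r_par <- r_of[[as.character(split_leaf)]]
    r_d <- r_par * radius_ratio * c(1 + eps, 1 - eps)
    for (k in 1:2) {
      id <- id + 1L
      rows[[length(rows) + 1L]] <-
        list(id = id, parent_id = split_leaf, r0 = r_d[k])
      r_of[as.character(id)] <- r_d[k]
    }
    leaves <- c(setdiff(leaves, split_leaf), id - 1L, id)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id, parent_id = r$parent_id, r0_cm = r$r0)))
  df$length_cm <- length_radius_ratio * df$r0_cm
  df$terminal <- !(df$id %in% df$parent_id)
  vessel_network(df[c("id", "parent_id", "length_cm", "r0_cm", "terminal")])
}

## root-to-vessel Poiseuille resistance along the path (cgs), per vessel id
path_poiseuille <- function(network, mu) {
  v <- network$vessels
  r_self <- 8 * mu * v$length_cm / (pi * v$r0_cm^4)
  parent_of <- stats::setNames(v$parent_id, v$id)
  res <- stats::setNames(numeric(nrow(v)), v$id)
  for (id in v$id) {
    cur <- id
    total <- 0
    while (!is.na(cur)) {
      total <- total + r_self[match(cur, v$id)]
      cur <- parent_of[[as.character(cur)]]
    }
    res[as.character(id)] <- total
  }
  res
}

#' Nominal Windkessel parameters for the terminal vessels
#'
#' Initializes the three-element Windkessel (RCR) outflow models so that the
#' network's total resistance reproduces the target mean pressure over mean
#' flow. The total distal resistance \eqn{R_{tot} = conv \cdot \bar p /
#' \bar q} (cgs) is distributed over terminal vessels with Poiseuille
#' weighting (conductance proportional to \eqn{r_0^4}), the root-to-leaf
#' Poiseuille resistance of the tree itself is subtracted from each
#' terminal's share, and the remainder is split into a proximal resistor
#' \code{R01 = proximal_fraction * R0} and distal resistor \code{R02}. The
#' capacitance is set by the peripheral time constant, \code{C0 = tau / R02}.
#'
#' @param network a \code{\link{vessel_network}}.
#' @param mean_flow cycle-averaged inflow, ml/s.
#' @param mean_pressure target mean arterial pressure, mmHg.
#' @param proximal_fraction fraction of each terminal resistance placed in
#'   the proximal resistor (matching the characteristic impedance), in
#'   (0, 1).
#' @param tau peripheral time constant \code{R02 * C0}, s.
#' @param constants \code{\link{physical_constants}}.
#' @return data frame with one row per terminal vessel: \code{id},
#'   \code{R01}, \code{R02} (g ml^-1 cm^-1 s^-1) and \code{C0}
#'   (ml cm s^2 g^-1). Note the capacitance is stored in the units that make
#'   \code{R02 * C0} a time.
#' @export
nominal_windkessel <- function(network, mean_flow, mean_pressure,
                               proximal_fraction = 0.2, tau = 0.025,
                               constants = physical_constants()) {
  stopifnot(mean_flow > 0, mean_pressure > 0,
            proximal_fraction > 0, proximal_fraction < 1, tau > 0)
  v <- network$vessels
  term <- v[v$terminal, , drop = FALSE]
  R_tot <- constants$conv * mean_pressure / mean_flow
  w <- term$r0_cm^4 / sum(term$r0_cm^4)
  R_target <- R_tot / w  # per-terminal total path resistance
  R_path <- path_poiseuille(network, constants$mu)[as.character(term$id)]
  R0 <- R_target - R_path
  if (any(R0 <= 0))
    stop("network Poiseuille resistance exceeds the target total ",
         "resistance for terminal vessel(s): ",
         paste(term$id[R0 <= 0], collapse = ", "))
  data.frame(id = term$id,
             R01 = proximal_fraction * R0,
             R02 = (1 - proximal_fraction) * R0,
             C0 = tau / ((1 - proximal_fraction) * R0))
}

#' Scale nominal Windkessel parameters
#'
#' Applies the global scaling factors \eqn{R_{1j} = \psi_1 R_{01j}},
#' \eqn{R_{2j} = \psi_2 R_{02j}}, \eqn{C_j = c\, C_{0j}} shared by all
#' terminal vessels.
#'
#' @param nominal output of \code{\link{nominal_windkessel}}.
#' @param psi1,psi2,cfac dimensionless scaling factors.
#' @return data frame with columns \code{id}, \code{R1}, \code{R2}, \code{C}.
#' @export
apply_scalings <- function(nominal, psi1, psi2, cfac) {
  out <- data.frame(id = nominal$id,
                    R1 = psi1 * nominal$R01,
                    R2 = psi2 * nominal$R02,
                    C = cfac * nominal$C0)
  if (any(out$R1 <= 0) || any(out$R2 <= 0) || any(out$C <= 0))
    stop("scaled Windkessel parameters must be strictly positive")
  out
}
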