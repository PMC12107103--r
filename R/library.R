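#' Generate a combinatorial DEL library specification
#'
#' Builds a desk-scale stand-in for a split-and-pool DNA-encoded library:
#' opaque building-block ids at each cycle position, with the compound
#' universe the Cartesian product across positions. Compound ids are the
#' position-wise building-block tuples joined with \code{"|"}.
#'
#' @param n_positions number of cycle positions (>= 1).
#' @param bbs_per_position integer vector (length \code{n_positions}, or a
#'   scalar recycled) of building-block counts per position (>= 1).
#' @param seed optional integer; accepted for interface symmetry with the
#'   other generators (id construction is deterministic).
#' @return object of class \code{del_library}: list with \code{n_positions},
#'   \code{building_blocks} (per-position character vectors), \code{bb}
#'   (data.frame of per-position ids, one row per compound) and
#'   \code{compound_id}.
#' @examples
#' lib <- gen_library(3, c(4, 5, 6))
#' nrow(lib$bb)   # 120
#' @export
gen_library <- function(n_positions, bbs_per_position, seed = NULL) {
  stopifnot(n_positions >= 1)
  if (length(bbs_per_position) == 1)
    bbs_per_position <- rep(bbs_per_position, n_positions)
  stopifnot(length(bbs_per_position) == n_positions,
            all(bbs_per_position >= 1))
  building_blocks <- lapply(seq_len(n_positions), function(p) {
    sprintf("P%d.B%03d", p, seq_len(bbs_per_position[p]))
  })
  names(building_blocks) <- paste0("pos", seq_len(n_positions))
  bb <- expand.grid(building_blocks, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  structure(list(n_positions = n_positions,
                 building_blocks = building_blocks,
                 bb = bb,
                 compound_id = compound_ids(bb)),
            class = "del_library")
}

#' Compound ids from a building-block tuple table
#'
#' @param bb data.frame of per-position building-block ids.
#' @return character vector of ids, positions joined with \code{"|"}.
#' @export
compound_ids <- function(bb) {
  do.call(paste, c(as.list(bb), sep = "|"))
}

#' @export
print.del_library <- function(x, ...) {
  cat(sprintf("DEL library: %d positions (%s), %s compounds\n",
              x$n_positions,
              paste(vapply(x$building_blocks, length, 1L), collapse = " x "),
              format(nrow(x$bb), big.mark = ",")))
  invisible(x)
}

#' Planted binder series for the selection generator
#'
#' A series is defined by fixing the building block at one or more positions;
#' every library compound matching the constraint is a binder with apo
#' dissociation constant \code{kd_apo} and per-cofactor cooperativity factors
#' \code{alpha}. Cofactors absent from \code{alpha} get factor 1
#' (no potentiation).
#'
#' @param positions named list/vector, e.g. \code{c(pos2 = "P2.B007")}.
#' @param kd_apo apo K_D in nM (> 0).
#' @param alpha named numeric of cooperativity factors per cofactor,
#'   e.g. \code{c(MTA = 20, SIN = 1)}.
#' @return object of class \code{del_series}.
#' @export
planted_series <- function(positions, kd_apo, alpha = c(MTA = 1, SIN = 1)) {
  stopifnot(kd_apo > 0, all(alpha > 0), !is.null(names(positions)))
  structure(list(positions = as.list(positions), kd_apo = kd_apo,
                 alpha = alpha),
            class = "del_series")
}

#' Ground truth for a simulated selection
#'
#' @param series list of \code{\link{planted_series}} objects.
#' @param background_capture per-molecule, per-round probability of
#'   nonspecific capture (matrix binding surviving the washes); in (0, 1).
#' @return object of class \code{del_ground_truth}.
#' @export
ground_truth <- function(series, background_capture = 0.005) {
  if (inherits(series, "del_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, TRUE, "del_series")),
            background_capture > 0, background_capture < 1)
  structure(list(series = series, background_capture = background_capture),
            class = "del_ground_truth")
}

#' Selection experiment configuration
#'
#' Defaults mirror the screening design: 6 uM protein, 60 uM cofactor, two
#' bind--wash--elute rounds. The SAM condition is modelled with a fixed
#' fraction of the nominal SAM present as MTA (spontaneous hydrolysis);
#' that contaminating MTA carries the series' MTA cooperativity.
#'
#' @param conditions character vector of cofactor conditions to simulate;
#'   any of \code{"none"} (apo), \code{"MTA"}, \code{"SIN"}, \code{"SAM"}.
#' @param protein_conc protein concentration (nM).
#' @param cofactor_conc cofactor concentration (nM).
#' @param rounds number of selection rounds (>= 1).
#' @param depth sequencing reads per condition (>= 0).
#' @param sam_mta_contamination fraction of nominal SAM present as MTA,
#'   in [0, 1).
#' @param dispersion Dirichlet-multinomial overdispersion; 0 gives plain
#'   multinomial sampling.
#' @param cofactor_kc named cofactor dissociation constants (nM).
#' @return object of class \code{selection_config}.
#' @export
selection_config <- function(conditions = c("MTA", "SIN"),
                             protein_conc = 6000,
                             cofactor_conc = 60000,
                             rounds = 2,
                             depth = 1e5,
                             sam_mta_contamination = 0.03,
                             dispersion = 0,
                             cofactor_kc = c(MTA = 5000, SIN = 5000,
                                             SAM = 5000)) {
  known <- c("none", "MTA", "SIN", "SAM")
  bad <- setdiff(conditions, known)
  if (length(bad))
    stop("unknown cofactor condition(s): ", paste(bad, collapse = ", "))
  stopifnot(rounds >= 1, depth >= 0, protein_conc >= 0, cofactor_conc >= 0,
            sam_mta_contamination >= 0, sam_mta_contamination < 1,
            dispersion >= 0)
  structure(list(conditions = conditions, protein_conc = protein_conc,
                 cofactor_conc = cofactor_conc, rounds = rounds,
                 depth = depth,
                 sam_mta_contamination = sam_mta_contamination,
                 dispersion = dispersion, cofactor_kc = cofactor_kc),
            class = "selection_config")
}
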