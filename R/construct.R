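#' The DNA-SNARE pulling construct
#'
#' Builds the mechanical model of the pulling construct used in magnetic
#' tweezers: two 510-bp dsDNA handles attached to the C-termini of
#' syntaxin-1A (K266C) and synaptobrevin-2 (I97C), with the two chains
#' covalently crosslinked near their N-termini (syx I202C, syb L32C) so that
#' tension runs C-terminus to C-terminus through the four-helix bundle.
#' Extension at a given force is the sum of the handle worm-like-chain
#' extensions, the worm-like-chain extension of whatever polypeptide is
#' unfolded in the current conformational state, and a force-independent
#' axial contribution of the remaining folded structure (treated as a rigid
#' rod along the pulling axis).
#'
#' Per-state folded-axial offsets default to the values produced by the
#' shipped one-time calibration (`scripts/calibrate_construct.R`), which
#' adjusts only these offsets so that the model state separations at 14 pN
#' equal 5.4 nm (linker-open), 13.9 nm (half-zippered) and 26.7 nm
#' (unzipped), and the SNAP-25 dissociation step at 16 pN equals 5 nm.
#' All other polymer parameters are pinned, not fitted.
#'
#' @param params List of construct parameters; defaults to the shipped
#'   human-editable config (`system.file("extdata", "construct_params.json",
#'   package = "snarezip")`). See that file for the schema.
#' @param layer_map Data frame with columns `chain`, `layer`, `residue`
#'   mapping leucine-zipper layers (-7..+8, layer 0 = ionic layer, syb R56 /
#'   syx Q226) to residues; defaults to the shipped table.
#' @return An object of class `snare_construct`.
#' @examples
#' con <- snare_construct()
#' state_delta(con, 14, "linker_open")
#' @export
snare_construct <- function(params = NULL, layer_map = NULL) {
  if (is.null(params)) {
    params <- jsonlite::read_json(
      system.file("extdata", "construct_params.json", package = "snarezip"),
      simplifyVector = TRUE)
  }
  if (is.null(layer_map)) {
    layer_map <- utils::read.delim(
      system.file("extdata", "layer_map.tsv", package = "snarezip"))
  }
  layer_map <- as_tibble(layer_map)
  stopifnot(all(c("chain", "layer", "residue") %in% names(layer_map)))

  chains <- params$chains
  for (ch in c("syx", "syb")) {
    rng <- chains[[ch]]
    att <- params$attachment[[ch]]
    xl <- params$crosslink[[ch]]
    if (att < rng[1] || att > rng[2] || xl < rng[1] || xl > rng[2]) {
      abort(sprintf("attachment/crosslink residue outside the %s chain range", ch))
    }
    res <- layer_map$residue[layer_map$chain == ch][order(layer_map$layer[layer_map$chain == ch])]
    if (any(diff(res) <= 0)) {
      abort(sprintf("layer map for %s is not strictly monotonic in residue", ch))
    }
  }

  obj <- structure(c(params, list(layer_map = layer_map)),
                   class = "snare_construct")
  obj$states <- .build_state_table(obj)
  obj
}

#' Conformational states of the tethered SNARE complex
#'
#' `snare_states()` lists the five modelled conformations in unfolding order.
#' `conformation_states()` tabulates, for a given construct, the number of
#' residues released as random coil on each chain in the tension path and the
#' folded-axial offset of each state.
#'
#' @return A character vector, or a tibble with one row per state.
#' @export
snare_states <- function() {
  c("fully_zippered", "linker_open", "half_zippered", "unzipped", "snap25_off")
}

.layer_residue <- function(construct, chain, layer) {
  lm <- construct$layer_map
  hit <- lm$residue[lm$chain == chain & lm$layer == layer]
  if (length(hit) != 1) {
    abort(sprintf("layer %+d is not in the layer map for chain %s", layer, chain))
  }
  hit
}

# Residues in the tension path between the crosslink and the handle
# attachment, exclusive of both anchor residues.
.coil_count <- function(from_res, to_res) max(0L, to_res - from_res - 1L)

.build_state_table <- function(construct) {
  att <- construct$attachment
  xl <- construct$crosslink
  syb_p8 <- .layer_residue(construct, "syb", 8)
  syx_p8 <- .layer_residue(construct, "syx", 8)
  syb_p2 <- .layer_residue(construct, "syb", 2)
  syx_p4 <- .layer_residue(construct, "syx", 4)
  syx_0 <- .layer_residue(construct, "syx", 0)

  tab <- tibble(
    state = snare_states(),
    # linker-open: linker domains (C-terminal of layer +8) random coil,
    # four-helix bundle intact. half-zippered: syb unfolded beyond +2,
    # Q-SNAREs beyond +4. unzipped: syb fully unraveled to the N-terminal
    # crosslink, Q-SNAREs unfolded to layer 0. snap25_off: SNAP-25
    # dissociated and syntaxin unraveled to the crosslink.
    unfolded_syb = c(0L,
                     .coil_count(syb_p8, att[["syb"]]),
                     .coil_count(syb_p2, att[["syb"]]),
                     .coil_count(xl[["syb"]], att[["syb"]]),
                     .coil_count(xl[["syb"]], att[["syb"]])),
    unfolded_syx = c(0L,
                     .coil_count(syx_p8, att[["syx"]]),
                     .coil_count(syx_p4, att[["syx"]]),
                     .coil_count(syx_0, att[["syx"]]),
                     .coil_count(xl[["syx"]], att[["syx"]]))
  )
  tab$n_unfolded <- tab$unfolded_syb + tab$unfolded_syx
  axial <- unlist(construct$state_axial_nm)
  if (any(axial < 0)) abort("folded-axial offsets must be >= 0")
  tab$axial_nm <- unname(axial[tab$state])
  tab
}

#' @rdname snare_states
#' @param construct A [snare_construct()].
#' @export
conformation_states <- function(construct) {
  stopifnot(inherits(construct, "snare_construct"))
  construct$states
}

.handle_segment <- function(construct) {
  dna_segment(bp = construct$handle_bp * construct$n_handles,
              persistence_length = construct$dna$persistence_length,
              contour_per_unit = construct$dna$nm_per_bp,
              stretch_modulus = construct$dna$stretch_modulus)
}

#' Construct extension per conformational state
#'
#' `state_extension()` predicts the total end-to-end extension of the
#' DNA-SNARE construct (handles + unfolded polypeptide + folded axial rod) at
#' the given force(s) for one conformational state. `state_delta()` is the
#' extension relative to the fully zippered state at the same force, the
#' quantity observed as discrete levels in bead-height traces.
#'
#' @param construct A [snare_construct()].
#' @param force Force in pN; vectorized.
#' @param state One of [snare_states()].
#' @return Extension in nm.
#' @export
state_extension <- function(construct, force, state) {
  stopifnot(inherits(construct, "snare_construct"))
  if (any(force < 0)) abort("force must be >= 0")
  row <- construct$states[construct$states$state == state, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown conformational state '%s'", state))
  }
  handles <- wlc_extension(force, .handle_segment(construct),
                           kBT = construct$kBT_pN_nm)
  frac <- .coil_fraction(force, construct$peptide$persistence_length,
                         kBT = construct$kBT_pN_nm)
  handles + row$n_unfolded * construct$peptide$nm_per_residue * frac +
    row$axial_nm
}

#' @rdname state_extension
#' @export
state_delta <- function(construct, force, state) {
  state_extension(construct, force, state) -
    state_extension(construct, force, "fully_zippered")
}

#' Residue span between two leucine-zipper layers
#'
#' Counts the residues between two layer positions on one chain, from the
#' construct's layer map. Symmetric in the order of the two layers.
#'
#' @param construct A [snare_construct()].
#' @param chain Chain id present in the layer map (e.g. `"syb"`, `"syx"`).
#' @param from_layer,to_layer Layer indices in -7..+8.
#' @return Integer residue count.
#' @export
layer_span_residues <- function(construct, chain, from_layer, to_layer) {
  stopifnot(inherits(construct, "snare_construct"))
  abs(.layer_residue(construct, chain, to_layer) -
        .layer_residue(construct, chain, from_layer))
}

#' @export
print.snare_construct <- function(x, ...) {
  cat("<snare_construct>\n")
  cat(sprintf("  handles: %d x %d bp dsDNA (P = %g nm, %g nm/bp, K = %g pN)\n",
              x$n_handles, x$handle_bp, x$dna$persistence_length,
              x$dna$nm_per_bp, x$dna$stretch_modulus))
  cat(sprintf("  peptide: P = %g nm, %g nm/residue\n",
              x$peptide$persistence_length, x$peptide$nm_per_residue))
  cat("  states (delta vs fully zippered at 14 pN):\n")
  for (s in snare_states()[-1]) {
    cat(sprintf("    %-14s %6.2f nm\n", s, state_delta(x, 14, s)))
  }
  invisible(x)
}
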