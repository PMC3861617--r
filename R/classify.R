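#' Kinetic class from dwell time
#'
#' Dwell-time classes: short (< 15 s), long (> 25 s and <= 30 s), very long
#' (> 30 s). The 15-25 s gap left between the short and long classes is
#' labelled `intermediate`, so the mapping is total and deterministic; the
#' very-long rule takes precedence over the long rule.
#'
#' @param dwell Dwell time(s), seconds (non-negative).
#' @return Factor with levels `short`, `intermediate`, `long`, `very_long`.
#' @examples
#' classify_dwell(c(12, 20, 28, 35))
#' @export
classify_dwell <- function(dwell) {
  if (any(!is.finite(dwell)) || any(dwell < 0)) {
    abort("dwell times must be finite and non-negative",
          class = "wntwave_input_error")
  }
  lab <- dplyr::case_when(
    dwell > 30 ~ "very_long",
    dwell > 25 ~ "long",
    dwell < 15 ~ "short",
    TRUE ~ "intermediate"
  )
  factor(lab, levels = c("short", "intermediate", "long", "very_long"))
}

#' Pairwise Mann-Whitney comparison of ligand dwell times
#'
#' Compares every ligand against a reference ligand (Wnt3A by default), and
#' additionally each adjacent pair of ligands ordered by descending median
#' dwell time. P-values are uncorrected by default, mirroring per-pair
#' reporting; set `adjust = "BH"` for Benjamini-Hochberg correction.
#'
#' @param data Data frame with a ligand column and a dwell-time column.
#' @param ligand,dwell Column names (default `ligand`, `dwell_s`).
#' @param reference Reference ligand label.
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Tibble: `ligand_a`, `ligand_b`, `comparison`, `n_a`, `n_b`, `u`,
#'   `p_value`, `method`.
#' @export
compare_ligands <- function(data, ligand = "ligand", dwell = "dwell_s",
                            reference = "Wnt3A", adjust = "none") {
  data <- as_tibble(data)
  g <- split(data[[dwell]], data[[ligand]])
  g <- purrr::map(g, function(v) v[is.finite(v)])
  if (length(g) < 2) {
    abort("need at least two ligand groups to compare",
          class = "wntwave_input_error")
  }
  if (any(lengths(g) < 3)) {
    abort("each ligand group needs >= 3 finite dwell times",
          class = "wntwave_input_error")
  }
  if (!reference %in% names(g)) {
    abort(paste0("reference ligand not present: ", reference),
          class = "wntwave_input_error")
  }
  others <- setdiff(names(g), reference)
  pairs <- tibble(ligand_a = reference, ligand_b = others,
                  comparison = "vs_reference")
  ord <- names(sort(vapply(g, median, numeric(1)), decreasing = TRUE))
  if (length(ord) >= 2) {
    desc <- tibble(ligand_a = ord[-length(ord)], ligand_b = ord[-1],
                   comparison = "descending_adjacent")
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    desc <- desc[!key(desc$ligand_a, desc$ligand_b) %in%
                   key(pairs$ligand_a, pairs$ligand_b), ]
    pairs <- dplyr::bind_rows(pairs, desc)
  }
  out <- purrr::pmap_dfr(pairs, function(ligand_a, ligand_b, comparison) {
    mw <- mann_whitney_u(g[[ligand_a]], g[[ligand_b]])
    tibble(ligand_a, ligand_b, comparison,
           n_a = mw$n_x, n_b = mw$n_y, u = mw$u,
           p_value = mw$p_value, method = mw$method)
  })
  if (adjust != "none") out$p_value <- stats::p.adjust(out$p_value, adjust)
  out
}
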