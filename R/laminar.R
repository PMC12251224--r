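## Current source density, layer assignment along the probe, layer
## averaging and amplitude normalization.

#' Current source density of a laminar voltage profile
#'
#' Plain second spatial difference along the probe (unit conductivity,
#' no spatial smoothing): `csd_i(t) = -(phi_{i-1} - 2 phi_i + phi_{i+1})
#' / spacing^2`, defined only at interior contacts. Under this sign
#' convention current sinks are negative (`convention = "sinks_negative"`).
#'
#' @param evoked_avg matrix `[contacts x time]`.
#' @param spacing_mm inter-contact spacing, mm.
#' @return a `csd_profile`: `csd [interior contacts x time]`, `contacts`
#'   (their indices in the input), `spacing_mm`, `convention`.
#' @export
compute_csd <- function(evoked_avg, spacing_mm) {
  nc <- nrow(evoked_avg)
  if (nc < 3) stop("CSD needs at least 3 contacts")
  inner <- 2:(nc - 1)
  csd <- -(evoked_avg[inner - 1, , drop = FALSE] -
             2 * evoked_avg[inner, , drop = FALSE] +
             evoked_avg[inner + 1, , drop = FALSE]) / spacing_mm^2
  structure(list(csd = csd, contacts = inner, spacing_mm = spacing_mm,
                 convention = "sinks_negative"),
            class = "csd_profile")
}

#' Default layer extents (contacts per layer) used to fill boundaries
#' @export
layer_priors <- function() {
  list(outside_ref_n = 3L, n_l1 = 2L, n_l23 = 5L, n_l4ab = 2L,
       n_l4c = 4L, n_l56 = 4L, field_rise_k = 2,
       sink_window_ms = c(20, 100), sink_sd_mult = 5)
}

.prior_map <- function(n_contacts, priors) {
  counts <- c(OUTSIDE = priors$outside_ref_n, L1 = priors$n_l1,
              L23 = priors$n_l23, L4AB = priors$n_l4ab,
              L4C = priors$n_l4c, L56 = priors$n_l56)
  counts <- c(counts, WM = max(0L, n_contacts - sum(counts)))
  rep(names(counts), counts)[seq_len(n_contacts)]
}

#' Assign probe contacts to cortical layers
#'
#' Codifies the combined rule used for laminar probes: the top of layer
#' 1 is the first contact where the stimulation field rises above the
#' outside-cortex reference (mean + k*SD of the topmost contacts); layer
#' 4C is centered on the interior contact showing the earliest
#' post-stimulus CSD sink (first crossing below `-sink_sd_mult` baseline
#' SDs inside `sink_window_ms`); the remaining boundaries are filled
#' from the prior layer extents. Falls back to the pure-prior map with a
#' warning when no field rise or no sink is found. Deterministic given
#' its inputs.
#'
#' @param csd a `csd_profile` of the Flash-condition evoked average, with
#'   a matching `t_ms` attribute or supplied via `t_ms`.
#' @param field a [field_profile()] data frame over the same contacts.
#' @param priors layer extents, see [layer_priors()].
#' @param t_ms time axis of the CSD columns, ms.
#' @return a `layer_map` data frame: `contact, depth_mm, label,
#'   provenance`.
#' @export
assign_layers <- function(csd, field, priors = layer_priors(),
                          t_ms = NULL) {
  stopifnot(inherits(csd, "csd_profile"))
  nc <- nrow(field)
  if (is.null(t_ms)) t_ms <- attr(csd, "t_ms")
  if (is.null(t_ms)) stop("supply the CSD time axis t_ms")
  fallback <- function(reason) {
    warning("layer assignment fell back to priors: ", reason)
    data.frame(contact = seq_len(nc),
               depth_mm = field$depth_mm,
               label = .prior_map(nc, priors),
               provenance = "prior", stringsAsFactors = FALSE)
  }
  ## layer-1 top boundary from the field rise
  ref <- field$efield_V_per_m[seq_len(priors$outside_ref_n)]
  thr <- mean(ref) + priors$field_rise_k * stats::sd(ref)
  rise <- which(field$efield_V_per_m > thr &
                  seq_len(nc) > priors$outside_ref_n)
  if (!length(rise) && stats::sd(ref) > 0)
    rise <- which(field$efield_V_per_m > thr)
  if (!length(rise)) return(fallback("no field rise found"))
  l1_start <- rise[1]
  ## earliest post-stimulus sink marks layer 4C; the noise scale is
  ## pooled across contacts (per-contact baseline SDs are too unstable
  ## to threshold against)
  win <- t_ms >= priors$sink_window_ms[1] & t_ms <= priors$sink_window_ms[2]
  base <- t_ms < 0
  s_pool <- stats::median(apply(csd$csd[, base, drop = FALSE], 1,
                                stats::sd))
  onset_t <- rep(Inf, nrow(csd$csd))
  if (s_pool > 0) for (i in seq_len(nrow(csd$csd))) {
    hit <- which(csd$csd[i, win] < -priors$sink_sd_mult * s_pool)
    if (length(hit)) onset_t[i] <- t_ms[win][hit[1]]
  }
  if (!any(is.finite(onset_t))) return(fallback("no early CSD sink found"))
  cand <- which(is.finite(onset_t) & onset_t <= min(onset_t) + 2)
  sink_contact <- csd$contacts[cand[which.max(
    vapply(cand, function(i) max(-csd$csd[i, win]), numeric(1)))]]
  ## place layer 4C so the sink contact sits at its center
  l4c_start <- sink_contact - floor((priors$n_l4c - 1) / 2)
  l4ab_start <- l4c_start - priors$n_l4ab
  l1_end <- l1_start + priors$n_l1 - 1
  if (l4ab_start <= l1_end + 1)
    return(fallback("field rise and CSD sink positions are inconsistent"))
  label <- rep("WM", nc)
  if (l1_start > 1) label[1:(l1_start - 1)] <- "OUTSIDE"
  label[l1_start:l1_end] <- "L1"
  label[(l1_end + 1):(l4ab_start - 1)] <- "L23"
  label[l4ab_start:(l4c_start - 1)] <- "L4AB"
  l4c_end <- min(l4c_start + priors$n_l4c - 1, nc)
  label[l4c_start:l4c_end] <- "L4C"
  if (l4c_end < nc) {
    l56_end <- min(l4c_end + priors$n_l56, nc)
    label[(l4c_end + 1):l56_end] <- "L56"
  }
  data.frame(contact = seq_len(nc), depth_mm = field$depth_mm,
             label = label, provenance = "csd/field",
             stringsAsFactors = FALSE)
}

#' Average epochs over the contacts of each layer
#'
#' Per-trial mean across the contacts belonging to each cortical layer
#' (`OUTSIDE`/`WM` contacts are kept as their own traces only if
#' requested). Trial count and keep mask are unchanged.
#'
#' @param epochs an `epoch_set` with contacts on the second dimension.
#' @param layers a `layer_map` data frame covering all epoch contacts.
#' @param which_layers labels to include (default: the cortical layers).
#' @return an `epoch_set` whose second dimension is layers (named).
#' @export
layer_average <- function(epochs, layers,
                          which_layers = c("L1", "L23", "L4AB", "L4C",
                                           "L56")) {
  d <- epochs$data
  if (nrow(layers) != dim(d)[2])
    stop("layer map does not cover the epoch contacts")
  present <- which_layers[which_layers %in% layers$label]
  dropped <- setdiff(which_layers, present)
  if (length(dropped))
    warning("layer(s) with no contacts omitted: ",
            paste(dropped, collapse = ", "))
  if (!length(present)) stop("no requested layer has any contact")
  out <- array(0, c(dim(d)[1], length(present), dim(d)[3]),
               dimnames = list(NULL, present, NULL))
  for (j in seq_along(present)) {
    idx <- which(layers$label == present[j])
    out[, j, ] <- if (length(idx) == 1) d[, idx, ] else
      apply(d[, idx, , drop = FALSE], c(1, 3), mean)
  }
  res <- epochs
  res$data <- out
  res$layer_labels <- present
  res
}

#' Normalize evoked traces to the layers 5/6 maximum
#'
#' Divides every trace by the maximum absolute value over the layers
#' 5/6 trace(s), so the layers 5/6 peak magnitude becomes 1. Idempotent
#' and invariant to global scaling.
#'
#' @param evoked matrix `[traces x time]`.
#' @param l56_rows row indices of the layers 5/6 trace(s).
#' @return normalized matrix with attribute `normalizer`.
#' @export
normalize_lfp <- function(evoked, l56_rows) {
  norm <- max(abs(evoked[l56_rows, , drop = FALSE]))
  if (norm == 0) stop("layers 5/6 trace is all zero; cannot normalize")
  out <- evoked / norm
  attr(out, "normalizer") <- norm
  out
}
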