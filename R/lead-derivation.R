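# Einthoven-triangle limb-lead derivation and ablation lead-group assembly.
#
# Any two limb leads determine the rest: III = II - I, aVR = -(I + II)/2,
# aVL = I - II/2, aVF = II - I/2. The lead groups are the ablation
# configurations of the protocol: full GAN reconstruction, GAN lead II (or III, or
# both) with Einthoven-derived limb leads, and the all-real references.

#' Derive limb leads from leads I and II
#'
#' @param leadI,leadII Equal-length numeric vectors (mV).
#' @return Named list with `III`, `aVR`, `aVL`, `aVF`.
#' @export
derive_from_I_II <- function(leadI, leadII) {
  if (length(leadI) != length(leadII))
    stop("derive_from_I_II: lead lengths differ")
  list(III = leadII - leadI,
       aVR = -(leadI + leadII) / 2,
       aVL = leadI - leadII / 2,
       aVF = leadII - leadI / 2)
}

#' Derive limb leads from leads I and III
#'
#' Lead II is recovered as I + III, then the augmented leads follow from
#' (I, II).
#'
#' @param leadI,leadIII Equal-length numeric vectors (mV).
#' @return Named list with `II`, `aVR`, `aVL`, `aVF`.
#' @export
derive_from_I_III <- function(leadI, leadIII) {
  if (length(leadI) != length(leadIII))
    stop("derive_from_I_III: lead lengths differ")
  leadII <- leadI + leadIII
  c(list(II = leadII), derive_from_I_II(leadI, leadII))[c("II", "aVR", "aVL", "aVF")]
}

#' The ablation lead-group identifiers
#'
#' @return Character vector: `gen12` (measured I + 11 GAN leads),
#'   `einthoven_II` (GAN lead II, Einthoven limb leads, GAN precordials),
#'   `einthoven_III`, `einthoven_II_III`, `real12`, `realI`.
#' @export
lead_groups <- function() {
  c("gen12", "einthoven_II", "einthoven_III", "einthoven_II_III",
    "real12", "realI")
}

#' Assemble one lead group for a single segment
#'
#' Builds the channel set of a lead group from the measured segment and the
#' GAN-reconstructed leads, recording per-lead provenance
#' (`measured` / `gan` / `einthoven`).
#'
#' * `gen12`: measured I, all 11 remaining leads from the GAN.
#' * `einthoven_II`: measured I, GAN II, limb leads III/aVR/aVL/aVF from
#'   (I, II) via Einthoven, precordials from the GAN.
#' * `einthoven_III`: measured I, GAN III, II = I + III and augmented leads
#'   via Einthoven, precordials from the GAN.
#' * `einthoven_II_III`: GAN II and GAN III both kept; aVR/aVL/aVF computed
#'   from (measured I, GAN II); the residual II - I - III (nonzero because
#'   the two leads are generated independently) is attached as attribute
#'   `einthoven_residual` (max absolute value).
#' * `real12` / `realI`: measured channels only.
#'
#' @param group One of [lead_groups()].
#' @param real Measured 12 x L signal matrix with rownames `ecg_leads()`
#'   (for `realI` only the `I` row is required).
#' @param gan Named list of GAN-generated leads (numeric vectors of length
#'   L), keyed by lead name. Only the leads the group needs are required.
#' @return Signal matrix (12 x L, or 1 x L for `realI`) with attribute
#'   `provenance` (named character vector).
#' @export
assemble_group <- function(group, real, gan = list()) {
  group <- match.arg(group, lead_groups())
  leads <- ecg_leads()
  L <- ncol(real)
  need_gan <- switch(group,
    gen12 = setdiff(leads, "I"),
    einthoven_II = c("II", paste0("V", 1:6)),
    einthoven_III = c("III", paste0("V", 1:6)),
    einthoven_II_III = c("II", "III", paste0("V", 1:6)),
    character(0))
  missing <- setdiff(need_gan, names(gan))
  if (length(missing))
    stop("missing GAN lead(s) for group ", group, ": ",
         paste(missing, collapse = ", "))
  if (group == "realI") {
    out <- real["I", , drop = FALSE]
    attr(out, "provenance") <- c(I = "measured")
    return(out)
  }
  prov <- setNames(rep("measured", 12), leads)
  out <- matrix(0, 12, L, dimnames = list(leads, NULL))
  if (group == "real12") {
    out[, ] <- real[leads, ]
    attr(out, "provenance") <- prov
    return(out)
  }
  out["I", ] <- real["I", ]
  for (v in need_gan) {
    out[v, ] <- gan[[v]]
    prov[v] <- "gan"
  }
  if (group == "einthoven_II") {
    d <- derive_from_I_II(out["I", ], out["II", ])
    for (nm in names(d)) { out[nm, ] <- d[[nm]]; prov[nm] <- "einthoven" }
  } else if (group == "einthoven_III") {
    d <- derive_from_I_III(out["I", ], out["III", ])
    for (nm in names(d)) { out[nm, ] <- d[[nm]]; prov[nm] <- "einthoven" }
  } else if (group == "einthoven_II_III") {
    d <- derive_from_I_II(out["I", ], out["II", ])
    for (nm in c("aVR", "aVL", "aVF")) { out[nm, ] <- d[[nm]]; prov[nm] <- "einthoven" }
    attr(out, "einthoven_residual") <-
      max(abs(out["II", ] - out["I", ] - out["III", ]))
  }
  attr(out, "provenance") <- prov
  out
}
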