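# Region table ("parcellation") construction.
#
# The full atlas follows the Destrieux-style cortical scheme plus
# Harvard-Oxford-style subcortex: 74 cortical structures per hemisphere,
# 7 subcortical structures per hemisphere, one cerebellum per hemisphere and
# a midline brain stem, i.e. 2*(74 + 7 + 1) + 1 = 165 regions. Only the
# regions of interest carry anatomically meaningful names; the remaining
# cortical structures are synthetic placeholder labels, since nothing
# downstream depends on their identity.

# Anterior-insula substructures analysed as ROIs: short insular gyrus,
# anterior segment of the circular sulcus of the insula, and the horizontal
# and vertical rami of the anterior segment of the lateral sulcus.
AINS_PARTS <- c("ShoInG", "ACirInS", "ALSHorp", "ALSVerp")
SUBCORTICAL <- c("NAcc", "Amg", "Caud", "Puta", "Pall", "Thal", "Hipp")
ROI_SHORT <- c("NAcc", "Amg", AINS_PARTS)

#' Build the brain region table
#'
#' Constructs the region table used by the connectome and metrics stages. At
#' the default `n_regions = 165` the composition is 74 cortical structures
#' per hemisphere (including the four anterior-insula ROI substructures),
#' 7 subcortical structures per hemisphere (including nucleus accumbens and
#' amygdala), one cerebellum per hemisphere, and the brain stem. Smaller
#' atlases (for simulation studies) always retain the 12 extended-reward ROIs
#' and the brain stem, padding with placeholder cortical regions.
#'
#' Region volumes (arbitrary units) are log-normal, subject-invariant, and
#' fixed by `volume_seed`.
#'
#' @param n_regions Total number of regions (>= 13).
#' @param volume_seed Seed fixing the synthetic region volumes.
#' @return A data.frame with columns `label`, `hemisphere`
#'   (left/right/midline), `class` (cortical/subcortical/cerebellum/
#'   brainstem), `volume`, `is_roi`.
#' @examples
#' atlas <- build_parcellation()
#' nrow(atlas)            # 165
#' sum(atlas$is_roi)      # 12
#' @export
build_parcellation <- function(n_regions = 165, volume_seed = 1234) {
  if (n_regions < 13) {
    stop("n_regions must be at least 13 (12 ROIs plus the brain stem)")
  }
  if (n_regions == 165) {
    cortical <- c(AINS_PARTS, sprintf("Ctx%02d", seq_len(70)))
    per_hemi <- c(cortical, SUBCORTICAL, "Cereb")
    cls <- c(rep("cortical", 74), rep("subcortical", 7), "cerebellum")
    labels <- c(paste0("L_", per_hemi), paste0("R_", per_hemi), "Brainstem")
    hemisphere <- c(rep("left", 82), rep("right", 82), "midline")
    class_vec <- c(cls, cls, "brainstem")
  } else {
    core <- c(AINS_PARTS, "NAcc", "Amg")
    core_cls <- c(rep("cortical", 4), rep("subcortical", 2))
    n_fill <- n_regions - 13L
    fill_lab <- if (n_fill > 0) {
      paste0(rep(c("L_", "R_"), length.out = n_fill),
             sprintf("Ctx%02d", ceiling(seq_len(n_fill) / 2)))
    } else {
      character(0)
    }
    labels <- c(paste0("L_", core), paste0("R_", core), fill_lab, "Brainstem")
    hemisphere <- c(rep("left", 6), rep("right", 6),
                    rep(c("left", "right"), length.out = n_fill), "midline")
    class_vec <- c(core_cls, core_cls, rep("cortical", n_fill), "brainstem")
  }
  short <- sub("^[LR]_", "", labels)
  is_roi <- short %in% ROI_SHORT & hemisphere != "midline"
  volumes <- with_seed(volume_seed, exp(rnorm(n_regions, log(3000), 0.3)))
  data.frame(
    label = labels,
    hemisphere = hemisphere,
    class = class_vec,
    volume = volumes,
    is_roi = is_roi,
    stringsAsFactors = FALSE
  )
}

#' Extended-reward ROI labels of a region table
#'
#' @param regions Region table from [build_parcellation()].
#' @return Character vector of the 12 ROI labels (left then right, NAcc and
#'   amygdala followed by the four anterior-insula substructures).
#' @export
roi_labels <- function(regions) {
  short <- sub("^[LR]_", "", regions$label)
  ord <- order(match(substr(regions$label, 1, 1), c("L", "R")),
               match(short, ROI_SHORT))
  regions$label[ord][regions$is_roi[ord]]
}

#' Locate ROI nodes within a region table
#'
#' Centrality metrics are computed on the whole network; this returns the
#' full matrices untouched together with the ordered indices of the ROI
#' nodes for which metrics are reported.
#'
#' @param matrices A list of connectivity matrices (passed through).
#' @param regions Region table.
#' @param rois Character vector of ROI labels; defaults to the 12
#'   extended-reward ROIs flagged in `regions`.
#' @return A list with elements `matrices` (unchanged) and `roi_indices`
#'   (integer positions of the ROIs in the region table, in `rois` order).
#' @export
restrict_to_rois <- function(matrices, regions, rois = NULL) {
  if (is.null(rois)) rois <- roi_labels(regions)
  idx <- match(rois, regions$label)
  if (anyNA(idx)) {
    stop("ROI label(s) not present in parcellation: ",
         paste(rois[is.na(idx)], collapse = ", "))
  }
  list(matrices = matrices, roi_indices = idx)
}
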