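# 44 bilateral cortical area names (Harvard-Oxford style). Together with the
# 3 midline areas below they give the 91 cortical labels of the shipped set.
.cortical_bilateral <- c(
  "Frontal Pole", "Insular Cortex", "Superior Frontal Gyrus",
  "Middle Frontal Gyrus", "Inferior Frontal Gyrus pars triangularis",
  "Inferior Frontal Gyrus pars opercularis", "Precentral Gyrus",
  "Temporal Pole", "Superior Temporal Gyrus anterior division",
  "Superior Temporal Gyrus posterior division",
  "Middle Temporal Gyrus anterior division",
  "Middle Temporal Gyrus posterior division",
  "Middle Temporal Gyrus temporooccipital part",
  "Inferior Temporal Gyrus anterior division",
  "Inferior Temporal Gyrus posterior division",
  "Inferior Temporal Gyrus temporooccipital part", "Postcentral Gyrus",
  "Superior Parietal Lobule", "Supramarginal Gyrus anterior division",
  "Supramarginal Gyrus posterior division", "Angular Gyrus",
  "Lateral Occipital Cortex superior division",
  "Lateral Occipital Cortex inferior division", "Intracalcarine Cortex",
  "Juxtapositional Lobule Cortex", "Paracingulate Gyrus",
  "Cingulate Gyrus posterior division", "Precuneous Cortex", "Cuneal Cortex",
  "Frontal Orbital Cortex", "Parahippocampal Gyrus anterior division",
  "Parahippocampal Gyrus posterior division", "Lingual Gyrus",
  "Temporal Fusiform Cortex anterior division",
  "Temporal Fusiform Cortex posterior division",
  "Temporal Occipital Fusiform Cortex", "Occipital Fusiform Gyrus",
  "Frontal Operculum Cortex", "Central Opercular Cortex",
  "Parietal Operculum Cortex", "Planum Polare", "Heschl's Gyrus",
  "Planum Temporale", "Occipital Pole"
)

.cortical_midline <- c(
  "Frontal Medial Cortex", "Subcallosal Cortex",
  "Cingulate Gyrus anterior division"
)

.subcortical_pairs <- c(
  "Thalamus", "Caudate", "Putamen", "Pallidum",
  "Hippocampus", "Amygdala", "Accumbens"
)

# AAL-style cerebellar parcellation: 9 hemispheric lobules x 2 + 8 vermis = 26
.cerebellar_hemi <- c(
  "Cerebelum Crus1", "Cerebelum Crus2", "Cerebelum 3", "Cerebelum 4 5",
  "Cerebelum 6", "Cerebelum 7b", "Cerebelum 8", "Cerebelum 9", "Cerebelum 10"
)
.cerebellar_vermis <- c(
  "Vermis 1 2", "Vermis 3", "Vermis 4 5", "Vermis 6", "Vermis 7", "Vermis 8",
  "Vermis 9", "Vermis 10"
)

.bilateral <- function(x) as.vector(t(outer(x, c("L", "R"), paste)))

#' Full 132-region ROI label set with subcortical seed subsets
#'
#' Returns the package's reference parcellation: 91 cortical and 15
#' subcortical labels (Harvard-Oxford-style naming) plus 26 cerebellar labels
#' (AAL-style naming), with the three seed subsets used for seed-restricted
#' connectivity analyses: 8 basal-ganglia ROIs (caudate, putamen, pallidum and
#' nucleus accumbens, both hemispheres), 2 thalamic ROIs, and all 26
#' cerebellar ROIs.
#'
#' The label strings are a synthetic stand-in constructed to match the
#' reference atlas counts; they are not an export of any atlas distribution.
#'
#' @return An object of class `roi_label_set`: a list with character vectors
#'   `cortical`, `subcortical`, `cerebellar`, `all` and a list `seed_subsets`
#'   with elements `basal_ganglia`, `thalamus`, `cerebellum`.
#' @examples
#' ls <- roi_label_set()
#' length(ls$all) # 132
#' lengths(ls$seed_subsets)
#' @export
roi_label_set <- function() {
  cortical <- c(.bilateral(.cortical_bilateral), .cortical_midline)
  subcortical <- c(.bilateral(.subcortical_pairs), "Brain-Stem")
  cerebellar <- c(.bilateral(.cerebellar_hemi), .cerebellar_vermis)
  out <- list(
    cortical = cortical,
    subcortical = subcortical,
    cerebellar = cerebellar,
    all = c(cortical, subcortical, cerebellar),
    seed_subsets = list(
      basal_ganglia = .bilateral(c("Caudate", "Putamen", "Pallidum", "Accumbens")),
      thalamus = .bilateral("Thalamus"),
      cerebellum = c(.bilateral(.cerebellar_hemi), .cerebellar_vermis)
    )
  )
  structure(out, class = "roi_label_set")
}

#' @export
print.roi_label_set <- function(x, ...) {
  cat("<roi_label_set>\n")
  cat(sprintf("  cortical: %d  subcortical: %d  cerebellar: %d (total %d)\n",
              length(x$cortical), length(x$subcortical), length(x$cerebellar),
              length(x$all)))
  cat(sprintf("  seed subsets: basal_ganglia (%d), thalamus (%d), cerebellum (%d)\n",
              length(x$seed_subsets$basal_ganglia),
              length(x$seed_subsets$thalamus),
              length(x$seed_subsets$cerebellum)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roi_label_set <- function(x, ...) {
  tibble::tibble(
    roi = x$all,
    lobe = rep(c("cortical", "subcortical", "cerebellar"),
               c(length(x$cortical), length(x$subcortical), length(x$cerebellar))),
    basal_ganglia = x$all %in% x$seed_subsets$basal_ganglia,
    thalamus = x$all %in% x$seed_subsets$thalamus,
    cerebellum = x$all %in% x$seed_subsets$cerebellum
  )
}
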