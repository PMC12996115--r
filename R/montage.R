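#' Idealized 32-channel 10-20 montage
#'
#' Unit-sphere electrode coordinates for the supported 32-channel 10-20
#' cap (FCz reference, Fpz ground, hence neither appears as a data
#' channel). Used by channel interpolation and topographic summaries.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit sphere,
#'   x right, y anterior, z superior).
#' @export
montage_1020 <- function() {
  path <- system.file("extdata", "montage_1020_32.csv", package = "faaloop",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Channel labels of the packaged montage, in canonical order
#' @export
montage_labels <- function() montage_1020()$label

#' Default homologous electrode pairs for frontal alpha asymmetry
#'
#' Left/right frontal and fronto-temporal pairs used for the FAA index:
#' F3/F4, F7/F8, FC5/FC6, FT9/FT10.
#'
#' @return data.frame with columns `left`, `right`, `name`.
#' @export
default_faa_pairs <- function() {
  data.frame(left  = c("F3", "F7", "FC5", "FT9"),
             right = c("F4", "F8", "FC6", "FT10"),
             name  = c("FAA_F3F4", "FAA_F7F8", "FAA_FC5FC6", "FAA_FT9FT10"),
             stringsAsFactors = FALSE)
}
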