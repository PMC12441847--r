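#' Cantilever sensor geometry
#'
#' Loads the packaged geometry description of the triangular NPO-10.B-style
#' micromechanical sensor used for nanomotion recordings: two prongs and a
#' triangular tip whose surfaces together form the area available for cell
#' attachment.
#'
#' @return A list with `model`, `n_prongs`, `prong_area_um2`,
#'   `tip_area_um2`, `total_area_um2`, `tolerance_um2`, `min_width_um`.
#' @export
cantilever_geometry <- function() {
  path <- system.file("extdata", "cantilever_npo10b.json",
                      package = "nanodst", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Total attachment area of a cantilever
#'
#' `n_prongs * prong_area + tip_area`, in square micrometers.
#'
#' @param geom A geometry list as returned by [cantilever_geometry()].
#' @return Area in um^2.
#' @export
attachment_area <- function(geom = cantilever_geometry()) {
  geom$n_prongs * geom$prong_area_um2 + geom$tip_area_um2
}
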