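# Anisotropy-aware binary morphology built on the exact Euclidean distance
# transform: the structuring element is a physical ball of radius r um,
# regardless of voxel shape.

edt_um <- function(mask_logical, spacing) {
  d <- dim(mask_logical)
  array(cpp_edt3d(as.logical(mask_logical), d, as.numeric(spacing)), d)
}

dilate_ball <- function(mask_logical, radius_um, spacing) {
  if (radius_um <= 0) return(mask_logical)
  edt_um(mask_logical, spacing) <= radius_um
}

erode_ball <- function(mask_logical, radius_um, spacing) {
  if (radius_um <= 0) return(mask_logical)
  mask_logical & edt_um(!mask_logical, spacing) > radius_um
}

close_ball <- function(mask_logical, radius_um, spacing) {
  erode_ball(dilate_ball(mask_logical, radius_um, spacing),
             radius_um, spacing)
}

# fill enclosed background cavities (6-connected background components not
# reaching the volume border); components of at least min_hole voxels are
# kept open
fill_holes3d <- function(mask_logical, min_hole = Inf) {
  d <- dim(mask_logical)
  bg <- !mask_logical
  lab <- array(cpp_label3d(bg, d, 6L), d)
  if (max(lab) == 0) return(mask_logical)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  enclosed <- setdiff(seq_len(max(lab)), border)
  fill <- enclosed[sizes[enclosed] < min_hole]
  if (length(fill)) mask_logical[lab %in% fill] <- TRUE
  mask_logical
}
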