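.onLoad <- function(libname, pkgname) {
  init_backend_state()
  register_op("filters.gaussian", .ref_gaussian)
  register_op("filters.median", .ref_median)
  register_op("transform.rescale", .ref_rescale)
  register_op("measure.label", .ref_label)
  register_op("ndimage.distance_transform_edt", .ref_edt)
  register_op("ndimage.local_maxima", .ref_local_max)
  register_op("morphology.binary_erosion", .ref_erosion)
  register_op("morphology.binary_dilation", .ref_dilation)
  register_op("morphology.binary_closing", .ref_closing)
  register_op("segmentation.watershed", .ref_watershed)
  invisible(NULL)
}
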