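#' @rdname VolumeGrid-class
#' @param x a \linkS4class{VolumeGrid} (or other object with intensities)
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("sliceAxis", function(x) standardGeneric("sliceAxis"))

#' @rdname RegionCluster-class
#' @param x a \linkS4class{RegionCluster}
#' @export
setGeneric("clusterMask", function(x) standardGeneric("clusterMask"))

#' @rdname RegionCluster-class
#' @export
setGeneric("clusterCentroid", function(x) standardGeneric("clusterCentroid"))

#' @rdname RegionCluster-class
#' @export
setGeneric("sliceSupport", function(x) standardGeneric("sliceSupport"))

#' @rdname AnatomicalFrame-class
#' @param x a \linkS4class{AnatomicalFrame}
#' @export
setGeneric("frameAxes", function(x) standardGeneric("frameAxes"))

#' @rdname AnatomicalFrame-class
#' @export
setGeneric("frameOrigin", function(x) standardGeneric("frameOrigin"))

#' @rdname AnatomicalFrame-class
#' @export
setGeneric("eyeLabels", function(x) standardGeneric("eyeLabels"))
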