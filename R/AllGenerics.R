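#' @rdname CellTable-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname CellTable-accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @rdname CellTable-accessors
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname CellTable-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname CellTable-accessors
#' @export
setGeneric("cellTypePalette", function(x) standardGeneric("cellTypePalette"))

#' @rdname CellTable-accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname CellTable-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CellTable-accessors
#' @export
setGeneric("cellGroups", function(x) standardGeneric("cellGroups"))

#' @rdname CellTable-accessors
#' @export
setGeneric("cellDomains", function(x) standardGeneric("cellDomains"))

#' @rdname NeighborGraph-accessors
#' @export
setGeneric("adjacencyList", function(x) standardGeneric("adjacencyList"))

#' @rdname NeighborGraph-accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname NeighborGraph-accessors
#' @export
setGeneric("neighborCounts", function(x) standardGeneric("neighborCounts"))

#' @rdname CommunityLabeling-accessors
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @rdname CommunityLabeling-accessors
#' @export
setGeneric("communitySizes", function(x) standardGeneric("communitySizes"))

#' @rdname CommunityLabeling-accessors
#' @export
setGeneric("typeComposition", function(x) standardGeneric("typeComposition"))

#' @rdname CommunityLabeling-accessors
#' @export
setGeneric("profileComposition",
           function(x) standardGeneric("profileComposition"))

#' @rdname CommunityLabeling-accessors
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname MergeTree-accessors
#' @export
setGeneric("mergeSteps", function(x) standardGeneric("mergeSteps"))
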