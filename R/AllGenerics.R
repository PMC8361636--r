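#' @rdname ExpressionDataset-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("hasLabels", function(x) standardGeneric("hasLabels"))

#' @rdname AssociationKB-class
#' @export
setGeneric("kbName", function(x) standardGeneric("kbName"))

#' @rdname AssociationKB-class
#' @export
setGeneric("kbRecords", function(x) standardGeneric("kbRecords"))

#' @rdname AssociationKB-class
#' @export
setGeneric("kbTerms", function(x) standardGeneric("kbTerms"))

#' @rdname NetworkKB-class
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname NetworkKB-class
#' @param pathway single pathway name.
#' @export
setGeneric("pathwayGraph",
           function(x, pathway) standardGeneric("pathwayGraph"))

#' @rdname NetworkKB-class
#' @export
setGeneric("pathwayMembers",
           function(x, pathway) standardGeneric("pathwayMembers"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname PathwayFeatureSet-class
#' @export
setGeneric("pathwayScores", function(x) standardGeneric("pathwayScores"))

#' @rdname PathwayFeatureSet-class
#' @export
setGeneric("activityMatrix", function(x) standardGeneric("activityMatrix"))
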