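#' Build a PopulationPanel
#'
#' @param groups named list mapping group name -> character vector of
#'   sample ids.
#' @param roles named character vector mapping quartet roles (subset of
#'   P1, P2, P3, O) to group names. P1 = recipient ancestral (bar),
#'   P2 = recipient derived (checker), P3 = donor, O = outgroup.
#' @return A [PopulationPanel-class].
#' @examples
#' p <- PopulationPanel(
#'   groups = list(bar = c("b1", "b2"), checker = c("c1", "c2"),
#'                 guinea = "g1", palumbus = "o1"),
#'   roles = c(P1 = "bar", P2 = "checker", P3 = "guinea", O = "palumbus"))
#' groupSamples(p, "bar")
#' @export
PopulationPanel <- function(groups, roles = character(0)) {
  df <- data.frame(
    sample = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE)
  new("PopulationPanel", samples = df, roles = roles)
}

#' Read a panel file
#'
#' Tab-separated with columns sample_id, group, role (role may be empty;
#' a role given for any sample in a group assigns that group to the role).
#'
#' @param path panel TSV.
#' @return A [PopulationPanel-class].
#' @export
readPanel <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample_id", "group", "role"),
                   colClasses = "character", fill = TRUE)
  groups <- split(df$sample_id, df$group)
  withRole <- df[nzchar(df$role), , drop = FALSE]
  roles <- setNames(withRole$group, withRole$role)
  roles <- roles[!duplicated(names(roles))]
  PopulationPanel(groups, roles)
}

#' @describeIn PopulationPanel sample ids belonging to a group.
#' @param x a \code{PopulationPanel}.
#' @param group group name.
#' @export
groupSamples <- function(x, group) {
  if (!group %in% x@samples$group) stop("no such group: ", group)
  x@samples$sample[x@samples$group == group]
}

#' @describeIn PopulationPanel sample ids filling a quartet role
#'   (errors if the role is unassigned or empty).
#' @param role one of "P1", "P2", "P3", "O".
#' @export
roleSamples <- function(x, role) {
  if (!role %in% names(x@roles))
    stop("quartet role ", role, " is not assigned in this panel")
  out <- groupSamples(x, x@roles[[role]])
  if (!length(out)) stop("quartet role ", role, " maps to an empty group")
  out
}

#' @describeIn PopulationPanel group names.
#' @export
groupNames <- function(x) unique(x@samples$group)

setMethod("show", "PopulationPanel", function(object) {
  tab <- table(object@samples$group)
  cat("PopulationPanel:", nrow(object@samples), "samples in",
      length(tab), "groups\n")
  for (g in names(tab)) {
    role <- names(object@roles)[object@roles == g]
    cat(sprintf("  %s: %d sample(s)%s\n", g, tab[[g]],
                if (length(role)) paste0(" [", role, "]") else ""))
  }
})

.checkQuartet <- function(panel) {
  for (r in c("P1", "P2", "P3", "O")) roleSamples(panel, r)
  invisible(TRUE)
}
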