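#' @useDynLib adaptmmn, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.field_levels <- c("thalamus", "core", "belt", "parabelt")

#' Construct a network anatomy
#'
#' An anatomy is the declarative description of the model's field structure:
#' which fields exist, at which hierarchical tier (thalamus, core, belt,
#' parabelt), how many tonotopic columns each holds, and which directed
#' field-to-field projections exist.  Weights are not part of the anatomy;
#' they are realised by [build_connectome()].
#'
#' @param fields data.frame with columns `name` (unique field labels),
#'   `level` (one of `"thalamus"`, `"core"`, `"belt"`, `"parabelt"`) and
#'   `n_columns` (positive integer, the number of tonotopic columns).
#' @param edges data.frame with columns `from`, `to` (field names) and
#'   `class` (`"feedforward"` or `"feedback"`).  Every feedforward edge must
#'   have a reciprocal feedback edge; extra feedback-only edges are allowed.
#' @return An object of class `network_anatomy`.
#' @seealso [default_anatomy()], [build_connectome()]
#' @export
new_anatomy <- function(fields, edges) {
  stopifnot(is.data.frame(fields), is.data.frame(edges))
  req_f <- c("name", "level", "n_columns")
  if (!all(req_f %in% names(fields)))
    stop("fields must have columns: ", paste(req_f, collapse = ", "))
  if (!all(c("from", "to", "class") %in% names(edges)))
    stop("edges must have columns: from, to, class")
  fields$name <- as.character(fields$name)
  fields$level <- as.character(fields$level)
  fields$n_columns <- as.integer(fields$n_columns)
  if (anyDuplicated(fields$name)) stop("field names must be unique")
  if (!all(fields$level %in% .field_levels))
    stop("unknown field level; must be one of: ",
         paste(.field_levels, collapse = ", "))
  if (any(fields$n_columns < 1L)) stop("n_columns must be positive")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$class <- as.character(edges$class)
  if (!all(edges$class %in% c("feedforward", "feedback")))
    stop("edge class must be 'feedforward' or 'feedback'")
  known <- c(edges$from, edges$to) %in% fields$name
  if (!all(known)) stop("edges refer to unknown fields")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  # reciprocity: each feedforward A->B needs a feedback B->A
  ff <- edges[edges$class == "feedforward", , drop = FALSE]
  fb <- edges[edges$class == "feedback", , drop = FALSE]
  need <- paste(ff$to, ff$from)
  have <- paste(fb$from, fb$to)
  if (!all(need %in% have))
    stop("every feedforward edge needs a reciprocal feedback edge")
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop("duplicate edges")
  rownames(fields) <- NULL
  rownames(edges) <- NULL
  structure(list(fields = fields, edges = edges), class = "network_anatomy")
}

#' Default auditory-cortex anatomy
#'
#' Builds the standard model: three core fields (R, RT, AI), eight belt
#' fields (AL, RTL, RTM, RM, MM, CM, CL, ML), two parabelt fields (RPB, CPB)
#' and the thalamic MGN field, 16 tonotopic columns each -- 208 cortical
#' columns and 224 units in total.  The MGN projects feedforward to the three
#' core fields; core fields project to their neighbouring belt fields; the
#' rostral parabelt interconnects with the anterior belt and the caudal
#' parabelt with the posterior belt.  Every feedforward projection is
#' reciprocated by a feedback projection, plus one extra feedback-only
#' projection CPB -> RM.
#'
#' The belt field sometimes labelled "RN" in the literature is named RM
#' (rostromedial belt) here; [read_anatomy_config()] accepts RN as an alias.
#'
#' @return A `network_anatomy`.
#' @examples
#' an <- default_anatomy()
#' sum(an$fields$n_columns)            # 224 units
#' @export
default_anatomy <- function() {
  core <- c("R", "RT", "AI")
  belt <- c("AL", "RTL", "RTM", "RM", "MM", "CM", "CL", "ML")
  pb <- c("RPB", "CPB")
  fields <- data.frame(
    name = c(core, belt, pb, "MGN"),
    level = c(rep("core", 3), rep("belt", 8), rep("parabelt", 2), "thalamus"),
    n_columns = 16L,
    stringsAsFactors = FALSE
  )
  ff <- rbind(
    data.frame(from = "MGN", to = core),
    data.frame(from = "AI", to = c("ML", "MM", "CL", "CM")),
    data.frame(from = "R",  to = c("AL", "RM", "ML", "MM")),
    data.frame(from = "RT", to = c("RTL", "RTM", "AL", "RM")),
    data.frame(from = c("AL", "RTL", "RTM", "RM"), to = "RPB"),
    data.frame(from = c("ML", "CL", "MM", "CM"), to = "CPB")
  )
  ff$class <- "feedforward"
  fb <- data.frame(from = ff$to, to = ff$from, class = "feedback")
  extra <- data.frame(from = "CPB", to = "RM", class = "feedback")
  new_anatomy(fields, rbind(ff, fb, extra))
}

#' Per-unit metadata table for an anatomy
#'
#' Units are numbered consecutively in field order; within a field, unit
#' order follows the tonotopic channel index 1..n_columns.
#'
#' @param anatomy a `network_anatomy`.
#' @return data.frame with columns `unit`, `field`, `level`, `channel` and
#'   `cortical` (logical; FALSE for thalamic units).
#' @export
anatomy_units <- function(anatomy) {
  stopifnot(inherits(anatomy, "network_anatomy"))
  f <- anatomy$fields
  n <- sum(f$n_columns)
  data.frame(
    unit = seq_len(n),
    field = rep(f$name, f$n_columns),
    level = rep(f$level, f$n_columns),
    channel = unlist(lapply(f$n_columns, seq_len), use.names = FALSE),
    cortical = rep(f$level != "thalamus", f$n_columns),
    stringsAsFactors = FALSE
  )
}

#' @export
print.network_anatomy <- function(x, ...) {
  u <- anatomy_units(x)
  cat("network_anatomy:", nrow(x$fields), "fields,", nrow(u), "units (",
      sum(u$cortical), "cortical )\n")
  tab <- table(x$fields$level)[intersect(.field_levels,
                                         unique(x$fields$level))]
  cat("  levels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  edges:", sum(x$edges$class == "feedforward"), "feedforward /",
      sum(x$edges$class == "feedback"), "feedback\n")
  invisible(x)
}

#' Read an anatomy from a YAML configuration file
#'
#' The YAML schema mirrors [new_anatomy()]: a `fields` list of
#' `{name, level, n_columns}` records (n_columns defaults to 16) and an
#' `edges` list of `{from, to, class}` records.  Feedback edges may be left
#' out, in which case every feedforward edge is reciprocated automatically.
#' The field alias "RN" is accepted and canonicalised to "RM".
#'
#' @param path path to a YAML file.
#' @return A `network_anatomy`.
#' @seealso [write_anatomy_config()]
#' @export
read_anatomy_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$fields) || is.null(cfg$edges))
    stop("anatomy config needs 'fields' and 'edges'")
  fields <- do.call(rbind, lapply(cfg$fields, function(f) {
    data.frame(name = f$name, level = f$level,
               n_columns = if (is.null(f$n_columns)) 16L else f$n_columns,
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(cfg$edges, function(e) {
    data.frame(from = e$from, to = e$to,
               class = if (is.null(e$class)) "feedforward" else e$class,
               stringsAsFactors = FALSE)
  }))
  # canonicalise the RN alias
  fields$name[fields$name == "RN"] <- "RM"
  edges$from[edges$from == "RN"] <- "RM"
  edges$to[edges$to == "RN"] <- "RM"
  ff <- edges[edges$class == "feedforward", , drop = FALSE]
  fb <- edges[edges$class == "feedback", , drop = FALSE]
  missing_fb <- !(paste(ff$to, ff$from) %in% paste(fb$from, fb$to))
  if (any(missing_fb)) {
    add <- data.frame(from = ff$to[missing_fb], to = ff$from[missing_fb],
                      class = "feedback", stringsAsFactors = FALSE)
    edges <- rbind(edges, add)
  }
  new_anatomy(fields, edges)
}

#' Write an anatomy to a YAML configuration file
#'
#' @param anatomy a `network_anatomy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anatomy_config <- function(anatomy, path) {
  stopifnot(inherits(anatomy, "network_anatomy"))
  cfg <- list(
    fields = lapply(seq_len(nrow(anatomy$fields)), function(i)
      as.list(anatomy$fields[i, ])),
    edges = lapply(seq_len(nrow(anatomy$edges)), function(i)
      as.list(anatomy$edges[i, ]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
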