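#' Connectivity parameters
#'
#' Gains and kernel widths used by [build_connectome()] to realise an anatomy
#' as weight matrices.  Between-field projections are topographic Gaussian
#' kernels truncated at 3*sigma and normalised so that the (interior-column)
#' outgoing weight per projection sums to the stated gain; kernel widths grow
#' up the hierarchy so tuning broadens from MGN towards the parabelt.
#' Within a field, each excitatory population excites itself (`w_self`), its
#' nearest-neighbour excitatory populations (`lat_exc` per side), and the
#' inhibitory populations of nearby columns (`gain_ie` spread over offsets
#' 0..`ie_span` with Gaussian width `sigma_ie`).  The inhibitory population
#' projects back only onto its own column's excitatory population (`w_ei`).
#'
#' Default magnitudes are the package's shipped calibration: gains selected
#' so that the full mismatch-negativity simulation battery exhibits its
#' qualitative orderings with margin across protocol seeds (see the methods
#' vignette for the procedure and [calibrate_gains()] for the single-tone
#' probe stage).  The defaults sit in a feedback-dominated, reverberant
#' regime: tone responses ride on slowly decaying recurrent activity rather
#' than returning promptly to rest.
#'
#' @param gain_ff named numeric: total feedforward gain per projection for
#'   the `thalamocortical`, `core_belt` and `belt_parabelt` level pairs.
#' @param fb_ratio feedback gain as a fraction of the feedforward gain for
#'   the same level pair.
#' @param sigma named numeric: Gaussian kernel widths (in channel units) for
#'   the same three level pairs.
#' @param w_self within-column excitatory self-feedback weight.
#' @param lat_exc intra-field lateral excitatory weight to each of the +/-1
#'   neighbouring columns.
#' @param gain_ie total intra-field lateral-inhibition drive (e -> i).
#' @param sigma_ie Gaussian width of the e -> i kernel (channel units).
#' @param ie_span maximum column offset reached by the e -> i kernel.
#' @param w_ei within-column inhibitory -> excitatory weight.
#' @return A list of class `connectivity_params`.
#' @export
connectivity_params <- function(gain_ff = c(thalamocortical = 4.64,
                                            core_belt = 2.82,
                                            belt_parabelt = 1.18),
                                fb_ratio = 0.82,
                                sigma = c(thalamocortical = 0.5,
                                          core_belt = 2.45,
                                          belt_parabelt = 2.20),
                                w_self = 0.57,
                                lat_exc = 0.057,
                                gain_ie = 3.59,
                                sigma_ie = 0.88,
                                ie_span = 3L,
                                w_ei = 0.56) {
  pairs <- c("thalamocortical", "core_belt", "belt_parabelt")
  gain_ff <- gain_ff[pairs]
  sigma <- sigma[pairs]
  if (anyNA(gain_ff) || anyNA(sigma))
    stop("gain_ff and sigma must name thalamocortical, core_belt, ",
         "belt_parabelt")
  p <- list(gain_ff = gain_ff, fb_ratio = fb_ratio, sigma = sigma,
            w_self = w_self, lat_exc = lat_exc, gain_ie = gain_ie,
            sigma_ie = sigma_ie, ie_span = as.integer(ie_span), w_ei = w_ei)
  num <- unlist(p[c("gain_ff", "fb_ratio", "w_self", "lat_exc", "gain_ie",
                    "w_ei")])
  if (any(num < 0)) stop("connectivity gains must be nonnegative")
  if (any(p$sigma <= 0) || p$sigma_ie <= 0) stop("kernel widths must be > 0")
  class(p) <- "connectivity_params"
  p
}

# level pair key for an edge (direction-independent)
.level_pair <- function(level_from, level_to) {
  key <- paste(sort(c(level_from, level_to)), collapse = "_")
  switch(key,
         "core_thalamus" = "thalamocortical",
         "belt_core" = "core_belt",
         "belt_parabelt" = "belt_parabelt",
         stop("no kernel defined for projection between levels ",
              level_from, " and ", level_to))
}

# truncated, normalised Gaussian kernel over integer channel offsets
.topo_kernel <- function(sigma, gain, n_columns) {
  k <- floor(3 * sigma)
  if (2 * k + 1 > n_columns)
    stop("topographic kernel wider than the field (3*sigma truncation ",
         "spans ", 2 * k + 1, " columns, field has ", n_columns, ")")
  d <- seq(-k, k)
  w <- exp(-d^2 / (2 * sigma^2))
  list(offsets = d, weights = gain * w / sum(w))
}

#' Build the weight matrices for an anatomy
#'
#' Realises a `network_anatomy` as the three weight matrices of the model:
#' `W_ee` (excitatory -> excitatory; within-column self-feedback, intra-field
#' lateral excitation, and topographic between-field projections), `W_ie`
#' (excitatory -> inhibitory; intra-field lateral inhibition drive) and
#' `W_ei` (inhibitory -> excitatory; strictly within-column, i.e. diagonal).
#' All weights are nonnegative -- inhibition enters through the sign of the
#' state-equation term, not through negative weights.  Every nonzero `W_ee`
#' entry carries a connection-class label (`feedforward`, `feedback` or
#' `intra_field`) used by the MEG read-out.
#'
#' @param anatomy a `network_anatomy`.
#' @param params a `connectivity_params`.
#' @return An object of class `connectome`: list with sparse matrices `W_ee`,
#'   `W_ie` (dgCMatrix, `[post, pre]` orientation), diagonal weights `w_ei`
#'   (numeric vector), an `entries` table of all nonzero `W_ee` entries with
#'   class labels, the per-unit metadata table `units`, and the generating
#'   `anatomy` and `params`.
#' @export
build_connectome <- function(anatomy, params = connectivity_params()) {
  stopifnot(inherits(anatomy, "network_anatomy"))
  if (!inherits(params, "connectivity_params"))
    stop("params must be a connectivity_params object")
  units <- anatomy_units(anatomy)
  n <- nrow(units)
  fstart <- c(0L, cumsum(anatomy$fields$n_columns))
  names(fstart) <- c(anatomy$fields$name, "_end")
  ncol_of <- stats::setNames(anatomy$fields$n_columns, anatomy$fields$name)
  level_of <- stats::setNames(anatomy$fields$level, anatomy$fields$name)
  unit_of <- function(field, col) fstart[[field]] + col

  pre <- integer(0); post <- integer(0); w <- numeric(0); cls <- character(0)
  add <- function(p_pre, p_post, p_w, p_cls) {
    pre <<- c(pre, p_pre); post <<- c(post, p_post)
    w <<- c(w, p_w); cls <<- c(cls, rep(p_cls, length(p_pre)))
  }

  # within-column self-feedback and intra-field lateral excitation
  for (f in anatomy$fields$name) {
    nc <- ncol_of[[f]]
    cols <- seq_len(nc)
    add(unit_of(f, cols), unit_of(f, cols), rep(params$w_self, nc),
        "intra_field")
    if (params$lat_exc > 0 && nc > 1) {
      for (d in c(-1L, 1L)) {
        src <- cols[cols + d >= 1 & cols + d <= nc]
        add(unit_of(f, src), unit_of(f, src + d),
            rep(params$lat_exc, length(src)), "intra_field")
      }
    }
  }

  # between-field topographic projections
  for (i in seq_len(nrow(anatomy$edges))) {
    e <- anatomy$edges[i, ]
    pair <- .level_pair(level_of[[e$from]], level_of[[e$to]])
    gain <- params$gain_ff[[pair]]
    if (e$class == "feedback") gain <- gain * params$fb_ratio
    if (gain <= 0) next
    nc_from <- ncol_of[[e$from]]; nc_to <- ncol_of[[e$to]]
    ker <- .topo_kernel(params$sigma[[pair]], gain, min(nc_from, nc_to))
    for (j in seq_along(ker$offsets)) {
      d <- ker$offsets[j]
      src <- seq_len(nc_from)
      tgt <- src + d
      keep <- tgt >= 1 & tgt <= nc_to
      if (!any(keep)) next
      add(unit_of(e$from, src[keep]), unit_of(e$to, tgt[keep]),
          rep(ker$weights[j], sum(keep)), e$class)
    }
  }

  entries <- data.frame(pre = pre, post = post, weight = w, class = cls,
                        stringsAsFactors = FALSE)
  if (anyDuplicated(entries[, c("pre", "post")]))
    stop("internal error: duplicate W_ee entries")
  W_ee <- Matrix::sparseMatrix(i = post, j = pre, x = w, dims = c(n, n))

  # intra-field lateral inhibition drive (e -> i)
  ie_d <- seq(-params$ie_span, params$ie_span)
  ie_w <- exp(-ie_d^2 / (2 * params$sigma_ie^2))
  ie_w <- params$gain_ie * ie_w / sum(ie_w)
  ipre <- integer(0); ipost <- integer(0); iw <- numeric(0)
  for (f in anatomy$fields$name) {
    nc <- ncol_of[[f]]
    if (2 * params$ie_span + 1 > nc)
      stop("lateral-inhibition kernel wider than field ", f)
    for (j in seq_along(ie_d)) {
      d <- ie_d[j]
      src <- seq_len(nc)
      tgt <- src + d
      keep <- tgt >= 1 & tgt <= nc
      ipre <- c(ipre, unit_of(f, src[keep]))
      ipost <- c(ipost, unit_of(f, tgt[keep]))
      iw <- c(iw, rep(ie_w[j], sum(keep)))
    }
  }
  W_ie <- Matrix::sparseMatrix(i = ipost, j = ipre, x = iw, dims = c(n, n))

  structure(list(W_ee = W_ee, W_ie = W_ie, w_ei = rep(params$w_ei, n),
                 entries = entries, units = units, anatomy = anatomy,
                 params = params),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("connectome:", nrow(x$units), "units;",
      nrow(x$entries), "W_ee entries (",
      paste(names(table(x$entries$class)), table(x$entries$class),
            sep = "=", collapse = ", "),
      ");", length(x$W_ie@x), "W_ie entries\n")
  invisible(x)
}

#' Export a connectome to plain-text files
#'
#' Writes `entries.tsv` (pre_field, pre_col, post_field, post_col, weight,
#' class for every nonzero entry of all three matrices, with full double
#' precision), `units.tsv`, and `meta.json` (fields, edges, connectivity
#' parameters) into a directory.  [read_connectome()] reconstructs an
#' identical connectome from these files.
#'
#' @param connectome a `connectome`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(connectome, dir) {
  stopifnot(inherits(connectome, "connectome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  u <- connectome$units
  ee <- connectome$entries
  ie_m <- Matrix::summary(connectome$W_ie)
  rows <- rbind(
    data.frame(matrix = "ee", pre = ee$pre, post = ee$post,
               weight = ee$weight, class = ee$class),
    data.frame(matrix = "ie", pre = ie_m$j, post = ie_m$i,
               weight = ie_m$x, class = "lateral_inhibition"),
    data.frame(matrix = "ei", pre = seq_len(nrow(u)), post = seq_len(nrow(u)),
               weight = connectome$w_ei, class = "within_column")
  )
  out <- data.frame(
    matrix = rows$matrix,
    pre_field = u$field[rows$pre], pre_col = u$channel[rows$pre],
    post_field = u$field[rows$post], post_col = u$channel[rows$post],
    weight = sprintf("%.17g", rows$weight),
    class = rows$class, stringsAsFactors = FALSE
  )
  utils::write.table(out, file.path(dir, "entries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(u, file.path(dir, "units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pl <- unclass(connectome$params)
  pl$gain_ff <- as.list(pl$gain_ff)   # keep names through JSON
  pl$sigma <- as.list(pl$sigma)
  meta <- list(fields = connectome$anatomy$fields,
               edges = connectome$anatomy$edges,
               params = pl)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a connectome written by [write_connectome()]
#'
#' @param dir directory containing `entries.tsv`, `units.tsv`, `meta.json`.
#' @return A `connectome`.
#' @export
read_connectome <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  anatomy <- new_anatomy(meta$fields, meta$edges)
  p <- meta$params
  params <- connectivity_params(
    gain_ff = unlist(p$gain_ff), fb_ratio = p$fb_ratio,
    sigma = unlist(p$sigma), w_self = p$w_self, lat_exc = p$lat_exc,
    gain_ie = p$gain_ie, sigma_ie = p$sigma_ie, ie_span = p$ie_span,
    w_ei = p$w_ei)
  units <- anatomy_units(anatomy)
  n <- nrow(units)
  tab <- utils::read.table(file.path(dir, "entries.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  fstart <- c(0L, cumsum(anatomy$fields$n_columns))
  names(fstart) <- c(anatomy$fields$name, "_end")
  pre <- fstart[tab$pre_field] + tab$pre_col
  post <- fstart[tab$post_field] + tab$post_col
  wgt <- as.numeric(tab$weight)
  is_ee <- tab$matrix == "ee"
  is_ie <- tab$matrix == "ie"
  is_ei <- tab$matrix == "ei"
  entries <- data.frame(pre = unname(pre[is_ee]), post = unname(post[is_ee]),
                        weight = wgt[is_ee], class = tab$class[is_ee],
                        stringsAsFactors = FALSE)
  W_ee <- Matrix::sparseMatrix(i = entries$post, j = entries$pre,
                               x = entries$weight, dims = c(n, n))
  W_ie <- Matrix::sparseMatrix(i = unname(post[is_ie]),
                               j = unname(pre[is_ie]),
                               x = wgt[is_ie], dims = c(n, n))
  w_ei <- numeric(n)
  w_ei[pre[is_ei]] <- wgt[is_ei]
  structure(list(W_ee = W_ee, W_ie = W_ie, w_ei = w_ei, entries = entries,
                 units = units, anatomy = anatomy, params = params),
            class = "connectome")
}
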