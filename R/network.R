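#' Vessel network container
#'
#' A `vessel_network` holds two tibbles -- `nodes` and `segments` -- plus the
#' axis-aligned `domain_box` bounding the tissue region of interest. All
#' coordinates are in µm; boxes are half-open `[lo, hi)`.
#'
#' `nodes` columns: `id`, `x`, `y`, `z`, `role` (`"interior"`, `"inlet"`,
#' `"outlet"`), `pressure` (mmHg, boundary nodes), `inlet_sao2` (fraction,
#' inlets only). `segments` columns: `id`, `from`, `to`, `radius_um`,
#' `flow_um3_s` (signed from -> to), `hematocrit`.
#'
#' @param nodes,segments Data frames with the columns above.
#' @param domain_box Numeric `2 x 3` matrix: rows `lo`, `hi`; columns x, y, z.
#' @return A validated `vessel_network`.
#' @export
vessel_network <- function(nodes, segments, domain_box) {
  nodes <- tibble::as_tibble(nodes)
  segments <- tibble::as_tibble(segments)
  need_n <- c("id", "x", "y", "z", "role")
  need_s <- c("id", "from", "to", "radius_um")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("vessel_network: nodes missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_s, names(segments))
  if (length(miss)) stop("vessel_network: segments missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"pressure" %in% names(nodes)) nodes$pressure <- NA_real_
  if (!"inlet_sao2" %in% names(nodes)) nodes$inlet_sao2 <- NA_real_
  if (!"flow_um3_s" %in% names(segments)) segments$flow_um3_s <- NA_real_
  if (!"hematocrit" %in% names(segments)) segments$hematocrit <- 0.45
  # all-NA columns read back from disk arrive as logical
  for (col in c("x", "y", "z", "pressure", "inlet_sao2")) {
    nodes[[col]] <- as.numeric(nodes[[col]])
  }
  for (col in c("radius_um", "flow_um3_s", "hematocrit")) {
    segments[[col]] <- as.numeric(segments[[col]])
  }
  domain_box <- as.matrix(domain_box)
  if (!all(dim(domain_box) == c(2, 3))) {
    stop("vessel_network: domain_box must be a 2 x 3 matrix (lo; hi).",
         call. = FALSE)
  }
  dimnames(domain_box) <- list(c("lo", "hi"), c("x", "y", "z"))
  net <- structure(list(nodes = nodes, segments = segments,
                        domain_box = domain_box),
                   class = "vessel_network")
  validate_network(net)
}

validate_network <- function(net) {
  nodes <- net$nodes
  segs <- net$segments
  if (anyDuplicated(nodes$id)) stop("vessel_network: duplicate node ids.",
                                    call. = FALSE)
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  if (any(!is.finite(pos))) {
    stop("vessel_network: non-finite node positions at rows ",
         paste(which(rowSums(!is.finite(pos)) > 0), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- which(!nodes$role %in% c("interior", "inlet", "outlet"))
  if (length(bad_role)) stop("vessel_network: invalid node role at rows ",
                             paste(bad_role, collapse = ", "), call. = FALSE)
  inl <- nodes$role == "inlet"
  bad_sat <- which(inl & !(is.finite(nodes$inlet_sao2) &
                           nodes$inlet_sao2 > 0 & nodes$inlet_sao2 <= 1))
  if (length(bad_sat)) {
    stop("vessel_network: inlets need inlet_sao2 in (0, 1]; bad rows ",
         paste(bad_sat, collapse = ", "), call. = FALSE)
  }
  if (nrow(segs)) {
    dangle <- which(!(segs$from %in% nodes$id) | !(segs$to %in% nodes$id))
    if (length(dangle)) {
      stop("vessel_network: segments reference missing nodes at rows ",
           paste(dangle, collapse = ", "), call. = FALSE)
    }
    bad_r <- which(!(is.finite(segs$radius_um) & segs$radius_um > 0))
    if (length(bad_r)) stop("vessel_network: nonpositive radius at rows ",
                            paste(bad_r, collapse = ", "), call. = FALSE)
    len <- segment_lengths(net)
    if (any(len <= 0)) stop("vessel_network: zero-length segments at rows ",
                            paste(which(len <= 0), collapse = ", "),
                            call. = FALSE)
  }
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  db <- x$domain_box
  cat(sprintf("<vessel_network> %d nodes, %d segments\n",
              nrow(x$nodes), nrow(x$segments)))
  cat(sprintf("  domain: %.0f x %.0f x %.0f um\n",
              db[2, 1] - db[1, 1], db[2, 2] - db[1, 2], db[2, 3] - db[1, 3]))
  cat(sprintf("  inlets: %d, outlets: %d\n",
              sum(x$nodes$role == "inlet"), sum(x$nodes$role == "outlet")))
  invisible(x)
}

node_xyz <- function(net, ids) {
  idx <- match(ids, net$nodes$id)
  as.matrix(net$nodes[idx, c("x", "y", "z")])
}

#' Segment lengths of a network (µm)
#' @param net A [vessel_network()].
#' @return Numeric vector, one length per segment row.
#' @export
segment_lengths <- function(net) {
  if (!nrow(net$segments)) return(numeric(0))
  a <- node_xyz(net, net$segments$from)
  b <- node_xyz(net, net$segments$to)
  sqrt(rowSums((b - a)^2))
}

#' Total vascular volume of a network (µm³)
#' @param net A [vessel_network()].
#' @param box Optional clip box (2 x 3 matrix); defaults to whole segments.
#' @return Scalar volume.
#' @export
vascular_volume <- function(net, box = NULL) {
  if (!nrow(net$segments)) return(0)
  len <- if (is.null(box)) segment_lengths(net) else {
    vapply(seq_len(nrow(net$segments)), function(i) {
      clip_segment_to_box(net, i, box)$length
    }, numeric(1))
  }
  sum(pi * net$segments$radius_um^2 * len)
}

#' Read a vessel network from disk
#'
#' Two on-disk layouts are supported: a CSV pair (`nodes.csv`,
#' `segments.csv` inside a directory, plus `domain.csv` with lo/hi rows)
#' and a single JSON file mirroring the same schema under keys
#' `nodes`, `segments`, `domain`.
#'
#' @param path Directory (csv-pair) or file (json).
#' @param format `"csv-pair"` or `"json"`; guessed from `path` when missing.
#' @return A [vessel_network()].
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv-pair"
  }
  format <- match.arg(format, c("csv-pair", "json"))
  if (format == "json") {
    if (!file.exists(path)) stop("read_network: no such file: ", path,
                                 call. = FALSE)
    obj <- jsonlite::fromJSON(path)
    dom <- matrix(unlist(obj$domain), nrow = 2, byrow = TRUE)
    vessel_network(obj$nodes, obj$segments, dom)
  } else {
    fn <- file.path(path, c("nodes.csv", "segments.csv", "domain.csv"))
    if (!all(file.exists(fn))) {
      stop("read_network: expected nodes.csv, segments.csv, domain.csv in ",
           path, call. = FALSE)
    }
    nodes <- readr::read_csv(fn[1], show_col_types = FALSE)
    segs <- readr::read_csv(fn[2], show_col_types = FALSE)
    dom <- as.matrix(readr::read_csv(fn[3], show_col_types = FALSE))
    vessel_network(nodes, segs, dom)
  }
}

#' Write a vessel network to disk
#'
#' Inverse of [read_network()]; column order is deterministic so that a
#' write/read round trip reproduces the network exactly.
#'
#' @param net A [vessel_network()].
#' @param path Output directory (csv-pair) or file (json).
#' @param format `"csv-pair"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv-pair"
  }
  format <- match.arg(format, c("csv-pair", "json"))
  ncols <- c("id", "x", "y", "z", "role", "pressure", "inlet_sao2")
  scols <- c("id", "from", "to", "radius_um", "flow_um3_s", "hematocrit")
  nodes <- net$nodes[, ncols]
  segs <- net$segments[, scols]
  if (format == "json") {
    obj <- list(nodes = nodes, segments = segs,
                domain = list(lo = unname(net$domain_box[1, ]),
                              hi = unname(net$domain_box[2, ])))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                         na = "null")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(nodes, file.path(path, "nodes.csv"))
    readr::write_csv(segs, file.path(path, "segments.csv"))
    dom <- tibble::as_tibble(net$domain_box)
    readr::write_csv(dom, file.path(path, "domain.csv"))
  }
  invisible(path)
}

#' Clip a segment to an axis-aligned box
#'
#' Exact line-box intersection under the half-open `[lo, hi)` convention.
#'
#' @param net A [vessel_network()].
#' @param i Segment row index.
#' @param box `2 x 3` matrix (lo; hi).
#' @return List with `length` (µm inside box), `volume` (µm³ inside box),
#'   `t0`, `t1` (entry/exit parameters on \[0,1\], or `NA` when outside).
#' @export
clip_segment_to_box <- function(net, i, box) {
  a <- as.numeric(node_xyz(net, net$segments$from[i]))
  b <- as.numeric(node_xyz(net, net$segments$to[i]))
  r <- net$segments$radius_um[i]
  d <- b - a
  t0 <- 0
  t1 <- 1
  for (k in 1:3) {
    if (d[k] == 0) {
      if (a[k] < box[1, k] || a[k] >= box[2, k]) {
        return(list(length = 0, volume = 0, t0 = NA_real_, t1 = NA_real_))
      }
    } else {
      tt <- sort(c((box[1, k] - a[k]) / d[k], (box[2, k] - a[k]) / d[k]))
      t0 <- max(t0, tt[1])
      t1 <- min(t1, tt[2])
    }
  }
  if (t1 <= t0) {
    return(list(length = 0, volume = 0, t0 = NA_real_, t1 = NA_real_))
  }
  len <- (t1 - t0) * sqrt(sum(d^2))
  list(length = len, volume = pi * r^2 * len, t0 = t0, t1 = t1)
}
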