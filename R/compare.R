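#' Compare two fitted S-system networks edge by edge
#'
#' Pairs every estimable coefficient position of two models sharing the same
#' variable list and classifies it: `same-sign` (both nonzero, same sign),
#' `sign-reversal` (both nonzero, opposite signs), `only-A` / `only-B`
#' (nonzero in one model only), or `absent` (zero in both). A coefficient with
#' absolute value at most `zero_tol` counts as zero. Positions masked in both
#' models are skipped; positions free in either model are compared (the two
#' fitted condition networks may differ in which coefficients they retain).
#'
#' @param model_a,model_b [ssys_model()] objects with identical variable
#'   lists.
#' @param zero_tol Absolute threshold below which a coefficient is zero.
#' @return An object of class `"ssys_netcmp"`: a data frame with columns
#'   `matrix`, `i` (receiver), `j` (giver), `coeff_a`, `coeff_b`, `status`.
#' @examples
#' cmp <- compare_networks(load_fixture_model("Ins2+/+"),
#'                         load_fixture_model("Ins2+/-"))
#' subset(cmp, status == "sign-reversal")
#' @export
compare_networks <- function(model_a, model_b, zero_tol = 1e-12) {
  stopifnot(inherits(model_a, "ssys_model"), inherits(model_b, "ssys_model"))
  if (!identical(model_a$variables, model_b$variables)) {
    stop("models must share an identical variable list")
  }
  vars <- model_a$variables
  n <- length(vars)
  one <- function(tag, A, B, mask) {
    idx <- which(t(!mask))
    ii <- ((idx - 1) %/% n) + 1
    jj <- ((idx - 1) %% n) + 1
    a <- A[cbind(ii, jj)]
    b <- B[cbind(ii, jj)]
    za <- abs(a) <= zero_tol
    zb <- abs(b) <= zero_tol
    status <- ifelse(za & zb, "absent",
              ifelse(za, "only-B",
              ifelse(zb, "only-A",
              ifelse(a * b < 0, "sign-reversal", "same-sign"))))
    data.frame(matrix = rep(tag, length(idx)), i = vars[ii], j = vars[jj],
               coeff_a = a, coeff_b = b, status = status,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one("g", model_a$g, model_b$g, model_a$mask_g & model_b$mask_g),
    one("h", model_a$h, model_b$h, model_a$mask_h & model_b$mask_h))
  rownames(out) <- NULL
  class(out) <- c("ssys_netcmp", "data.frame")
  out
}

#' @export
print.ssys_netcmp <- function(x, ...) {
  nrev <- sum(x$status == "sign-reversal")
  cat("Network comparison over", nrow(x), "coefficient positions;",
      nrev, "sign reversal(s)\n")
  print.data.frame(x[x$status != "absent", , drop = FALSE], digits = 3, ...)
  invisible(x)
}

#' Export a fitted network as SIF or GraphML
#'
#' Each nonzero coefficient becomes a directed edge from the giving variable
#' `j` to the receiving variable `i`; a positive coefficient is an activation
#' edge, a negative one an inhibition edge. The SIF format writes one line
#' `source interaction target` per edge; GraphML (written with \pkg{igraph})
#' carries `matrix`, `coefficient`, `sign` and — when a sensitivity report is
#' supplied — `sensitivity` (scaled score) edge attributes.
#'
#' @param model An [ssys_model()].
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"` (default: inferred from the file
#'   extension, falling back to SIF).
#' @param report Optional `"ssys_sensitivity"` report whose scaled scores are
#'   attached to matching edges.
#' @return `path`, invisibly.
#' @export
export_network <- function(model, path, format = NULL, report = NULL) {
  stopifnot(inherits(model, "ssys_model"))
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "sif"
  }
  format <- match.arg(format, c("sif", "graphml"))
  ed <- rbind(coeff_positions(model$g, model$mask_g, "g"),
              coeff_positions(model$h, model$mask_h, "h"))
  vals <- numeric(nrow(ed))
  if (nrow(ed) > 0) {
    for (k in seq_len(nrow(ed))) {
      m <- if (ed$matrix[k] == "g") model$g else model$h
      vals[k] <- m[ed$ii[k], ed$jj[k]]
    }
  }
  if (format == "sif") {
    lines <- if (nrow(ed) > 0) {
      paste(model$variables[ed$jj],
            ifelse(vals > 0, "activates", "inhibits"),
            model$variables[ed$ii], sep = "\t")
    } else {
      # isolated nodes: SIF convention is a line with the node name alone
      model$variables
    }
    writeLines(lines, path)
  } else {
    graph <- igraph::make_empty_graph(n = length(model$variables),
                                      directed = TRUE)
    graph <- igraph::set_vertex_attr(graph, "name", value = model$variables)
    if (nrow(ed) > 0) {
      edges <- rbind(model$variables[ed$jj], model$variables[ed$ii])
      graph <- igraph::add_edges(graph, as.vector(edges))
      graph <- igraph::set_edge_attr(graph, "matrix", value = ed$matrix)
      graph <- igraph::set_edge_attr(graph, "coefficient", value = vals)
      graph <- igraph::set_edge_attr(graph, "sign",
                                     value = ifelse(vals > 0, "activation",
                                                    "inhibition"))
      if (!is.null(report)) {
        key_e <- paste(ed$matrix, model$variables[ed$ii],
                       model$variables[ed$jj])
        key_r <- paste(report$matrix, report$i, report$j)
        graph <- igraph::set_edge_attr(
          graph, "sensitivity", value = report$scaled[match(key_e, key_r)])
      }
    }
    igraph::write_graph(graph, path, format = "graphml")
  }
  invisible(path)
}
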