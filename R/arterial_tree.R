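#' Load an arterial tree definition
#'
#' Reads a JSON tree-definition file describing a bifurcating binary tree of
#' tapering elastic vessels. Each vessel record carries an id, a name, its
#' length and its inlet/outlet radii at the reference pressure; terminal
#' vessels additionally carry the nominal three-element Windkessel parameters
#' of the vascular bed they feed. The packaged nominal tree
#' (`system.file("extdata", "arterial_tree_55.json", package = "pulsewave")`)
#' has the 55 larger systemic arteries.
#'
#' @param path path to a tree definition JSON file.
#' @return an object of class `arterial_tree`: a list with elements
#'   `vessels` (data frame: id, name, length_cm, r_in_cm, r_out_cm, parent,
#'   d1, d2, terminal), `windkessel` (data frame of nominal terminal R1, R2,
#'   C in CGS units and p_out_mmHg), `named_sites`, `root`,
#'   `nominal_height_cm`, `height_cm` (current height, equals nominal on
#'   load) and `p_ref_mmHg`.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed tree file '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(raw$vessels)) stop("malformed tree file: no 'vessels' field")
  n <- length(raw$vessels)
  get_num <- function(rec, fld) {
    v <- rec[[fld]]
    if (is.null(v) || !is.numeric(v))
      stop("malformed vessel record (id=", rec$id %||% "?",
           "): missing numeric field '", fld, "'")
    as.numeric(v)
  }
  vs <- data.frame(
    id = vapply(raw$vessels, function(r) as.integer(get_num(r, "id")), 1L),
    name = vapply(raw$vessels, function(r) as.character(r$name %||% ""), ""),
    length_cm = vapply(raw$vessels, get_num, 1, fld = "length_cm"),
    r_in_cm = vapply(raw$vessels, get_num, 1, fld = "r_in_cm"),
    r_out_cm = vapply(raw$vessels, get_num, 1, fld = "r_out_cm"),
    stringsAsFactors = FALSE
  )
  daughters <- lapply(raw$vessels, function(r)
    as.integer(unlist(r$daughters %||% integer(0))))
  vs$d1 <- vapply(daughters, function(d) if (length(d) >= 1) d[1] else NA_integer_, 1L)
  vs$d2 <- vapply(daughters, function(d) if (length(d) >= 2) d[2] else NA_integer_, 1L)
  nd <- lengths(daughters)
  bad <- which(!(nd %in% c(0L, 2L)))
  if (length(bad))
    stop("topology violation: vessel id ", vs$id[bad[1]], " ('",
         vs$name[bad[1]], "') has ", nd[bad[1]],
         " daughter(s); vessels must have 0 or 2")
  vs$terminal <- nd == 0L

  wk <- do.call(rbind, lapply(which(vs$terminal), function(i) {
    w <- raw$vessels[[i]]$windkessel
    if (is.null(w))
      stop("terminal vessel id ", vs$id[i], " has no windkessel record")
    data.frame(id = vs$id[i], R1 = as.numeric(w$R1), R2 = as.numeric(w$R2),
               C = as.numeric(w$C), p_out_mmHg = as.numeric(w$p_out_mmHg))
  }))

  sites <- lapply(raw$named_sites %||% list(), function(s)
    list(vessel = as.integer(s$vessel), position = as.numeric(s$position)))

  tree <- structure(list(
    vessels = vs, windkessel = wk, named_sites = sites,
    root = as.integer(raw$root %||% vs$id[1]),
    nominal_height_cm = as.numeric(raw$nominal_height_cm %||% 176),
    height_cm = as.numeric(raw$nominal_height_cm %||% 176),
    p_ref_mmHg = as.numeric(raw$p_ref_mmHg %||% 97),
    name = raw$name %||% basename(path)
  ), class = "arterial_tree")
  validate_tree(tree)
  tree
}

#' The packaged nominal 55-vessel systemic tree
#' @return an `arterial_tree` with 55 vessels.
#' @export
nominal_tree <- function() {
  load_tree(system.file("extdata", "arterial_tree_55.json",
                        package = "pulsewave", mustWork = TRUE))
}

#' Validate an arterial tree
#'
#' Checks all structural invariants: unique ids, positive lengths, tapering
#' radii (`r_in >= r_out > 0`), 0-or-2 daughters, a single root, connectivity
#' and acyclicity.
#'
#' @param tree an `arterial_tree`.
#' @return the tree, invisibly; errors on any violation.
#' @export
validate_tree <- function(tree) {
  vs <- tree$vessels
  if (anyDuplicated(vs$id)) stop("duplicate vessel ids")
  if (any(vs$length_cm <= 0)) stop("non-positive vessel length (id=",
                                   vs$id[which(vs$length_cm <= 0)[1]], ")")
  if (any(vs$r_out_cm <= 0) || any(vs$r_in_cm < vs$r_out_cm))
    stop("radius invariant violated (need r_in >= r_out > 0) at id=",
         vs$id[which(vs$r_out_cm <= 0 | vs$r_in_cm < vs$r_out_cm)[1]])
  kids <- c(vs$d1[!is.na(vs$d1)], vs$d2[!is.na(vs$d2)])
  if (!all(kids %in% vs$id)) stop("daughter id refers to unknown vessel")
  if (anyDuplicated(kids)) stop("vessel with two parents")
  roots <- setdiff(vs$id, kids)
  if (length(roots) != 1) stop("tree must have exactly one root, found ",
                               length(roots))
  if (roots != tree$root) stop("declared root (", tree$root,
                               ") is not the actual root (", roots, ")")
  ## connectivity/acyclicity: walk from root, must visit every vessel once
  seen <- integer(0)
  stack <- tree$root
  idx <- match(vs$id, vs$id)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% seen) stop("cycle detected at vessel id ", v)
    seen <- c(seen, v)
    i <- match(v, vs$id)
    if (!vs$terminal[i]) stack <- c(stack, vs$d1[i], vs$d2[i])
  }
  if (length(seen) != nrow(vs)) stop("tree is not connected: ",
                                     nrow(vs) - length(seen),
                                     " vessel(s) unreachable from root")
  for (nm in names(tree$named_sites)) {
    s <- tree$named_sites[[nm]]
    if (!(s$vessel %in% vs$id)) stop("named site '", nm,
                                     "' refers to unknown vessel ", s$vessel)
    if (s$position < 0 || s$position > 1)
      stop("named site '", nm, "' position outside [0,1]")
  }
  invisible(tree)
}

#' Scale a tree to a subject's height
#'
#' Vessel lengths are multiplied by `height / nominal_height`; radii, the
#' topology, the named sites and the terminal Windkessel data are untouched.
#' Body height mostly changes path lengths (and hence wave transit times),
#' which is why the scaling is applied to lengths only.
#'
#' @param tree an `arterial_tree`.
#' @param height_cm subject height in cm.
#' @param bounds admissible height range, default 120-220 cm.
#' @return the scaled `arterial_tree` (its `height_cm` records the subject).
#' @export
scale_tree_to_height <- function(tree, height_cm, bounds = c(120, 220)) {
  if (!is.numeric(height_cm) || length(height_cm) != 1 ||
      height_cm < bounds[1] || height_cm > bounds[2])
    stop("height ", height_cm, " cm outside admissible range [",
         bounds[1], ", ", bounds[2], "]")
  fac <- height_cm / tree$nominal_height_cm
  tree$vessels$length_cm <- tree$vessels$length_cm * fac
  tree$height_cm <- height_cm
  tree
}

## reference radius at distance x (cm) from the inlet: linear taper
vessel_r0 <- function(tree, id, x) {
  i <- match(id, tree$vessels$id)
  L <- tree$vessels$length_cm[i]
  if (any(x < 0 | x > L)) stop("position outside vessel")
  tree$vessels$r_in_cm[i] + (tree$vessels$r_out_cm[i] -
                               tree$vessels$r_in_cm[i]) * x / L
}

## resolve a site given as a name or list(vessel, position)
resolve_site <- function(tree, site) {
  if (is.character(site)) {
    s <- tree$named_sites[[site]]
    if (is.null(s)) stop("unknown named site '", site, "'; available: ",
                         paste(names(tree$named_sites), collapse = ", "))
    return(s)
  }
  if (is.list(site) && !is.null(site$vessel) && !is.null(site$position))
    return(list(vessel = as.integer(site$vessel),
                position = as.numeric(site$position)))
  stop("a site must be a named-site string or list(vessel=, position=)")
}

## ids along the path root -> vessel (inclusive)
path_to_root <- function(tree, id) {
  vs <- tree$vessels
  parent <- rep(NA_integer_, nrow(vs))
  parent[match(vs$d1[!is.na(vs$d1)], vs$id)] <- vs$id[!is.na(vs$d1)]
  parent[match(vs$d2[!is.na(vs$d2)], vs$id)] <- vs$id[!is.na(vs$d2)]
  path <- id
  while (!is.na(parent[match(path[1], vs$id)]))
    path <- c(parent[match(path[1], vs$id)], path)
  path
}

#' Path length between two sites along the tree
#'
#' Both sites must lie on a common root-to-leaf path (the usual case for pulse
#' wave velocity paths such as aortic arch to femoral artery); the distance is
#' the sum of the scaled vessel-segment lengths between them.
#'
#' @param tree an `arterial_tree`.
#' @param site_a,site_b site names or `list(vessel=, position=)`.
#' @return distance in cm.
#' @export
site_distance <- function(tree, site_a, site_b) {
  a <- resolve_site(tree, site_a); b <- resolve_site(tree, site_b)
  pa <- path_to_root(tree, a$vessel); pb <- path_to_root(tree, b$vessel)
  ## the deeper site must have the shallower one's vessel on its root path
  if (a$vessel %in% pb) { tmp <- a; a <- b; b <- tmp; tmp <- pa; pa <- pb; pb <- tmp }
  if (!(b$vessel %in% pa) && a$vessel != b$vessel)
    stop("sites are not on a common root-to-leaf path")
  vs <- tree$vessels
  len <- function(id) vs$length_cm[match(id, vs$id)]
  if (a$vessel == b$vessel) {
    d <- abs(a$position - b$position) * len(a$vessel)
  } else {
    ## b is the ancestor: distance from b's position to end of b, plus full
    ## intermediate vessels, plus a's position from its inlet
    seg <- pa[(match(b$vessel, pa) + 1):length(pa)]
    inner <- setdiff(seg, a$vessel)
    d <- (1 - b$position) * len(b$vessel) + sum(vapply(inner, len, 1)) +
      a$position * len(a$vessel)
  }
  if (d == 0) stop("zero distance between sites")
  d
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat("<arterial_tree> '", x$name, "': ", nrow(x$vessels), " vessels (",
      sum(x$vessels$terminal), " terminal), height ", x$height_cm,
      " cm (nominal ", x$nominal_height_cm, "), p_ref ", x$p_ref_mmHg,
      " mmHg\n", sep = "")
  invisible(x)
}
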