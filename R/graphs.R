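# Ready-made analysis graphs mirroring the two case studies: largest-cluster
# identification, recurrent cluster tracking, colour graduation, and the
# MCG-1 hydrate pipeline. Each returns an ordinary md_graph the caller can
# save, edit or execute.

#' Largest-cluster identification graph
#'
#' positions -> neighbour list -> connected components -> mode mask, with
#' every intermediate saved as a recorded attribute for inspection
#' (`n_neighbors`, `group_id`, `largest_mask`).
#'
#' @param cutoff Neighbour cutoff, angstrom.
#' @return An [md_graph()].
#' @export
largest_cluster_graph <- function(cutoff) {
  md_graph(
    nodes = list(
      graph_node("pos", "positions"),
      graph_node("nbr", "list_neighbors", list(cutoff = cutoff)),
      graph_node("grp", "group_list"),
      graph_node("mask", "mode_mask"),
      graph_node("save_counts", "set_attribute", list(name = "n_neighbors")),
      graph_node("save_groups", "set_attribute", list(name = "group_id")),
      graph_node("save_mask", "set_attribute", list(name = "largest_mask"))),
    connections = list(
      connection("pos", "positions", "nbr", "positions"),
      connection("nbr", "edges", "grp", "edges"),
      connection("grp", "labels", "mask", "labels"),
      connection("nbr", "counts", "save_counts", "value"),
      connection("grp", "labels", "save_groups", "value"),
      connection("mask", "mask", "save_mask", "value")),
    attributes = list(
      attr_decl("n_neighbors", record = TRUE),
      attr_decl("group_id", record = TRUE),
      attr_decl("largest_mask", record = TRUE)))
}

#' Recurrent cluster-tracking graph
#'
#' The tracking node reads the `current_label` attribute written on the
#' previous frame and writes it back after relabelling against this frame's
#' components - the same attribute is both input and output, which is what
#' makes the graph recurrent. A second recorded attribute keeps the label
#' for every frame. Run it backward from the final frame (with
#' `current_label` initialized to the final largest-cluster mask) to
#' recover when and how the cluster formed.
#'
#' @param cutoff Neighbour cutoff, angstrom.
#' @param init Initial per-atom value of `current_label` (e.g. the final
#'   frame's [mode_mask()]).
#' @param min_size Minimum group size treated as a cluster.
#' @param direction Execution direction.
#' @return An [md_graph()].
#' @export
tracking_graph <- function(cutoff, init = 0, min_size = 2,
                           direction = "backward") {
  md_graph(
    nodes = list(
      graph_node("pos", "positions"),
      graph_node("nbr", "list_neighbors", list(cutoff = cutoff)),
      graph_node("grp", "group_list"),
      graph_node("prev", "get_attribute", list(name = "current_label")),
      graph_node("track", "track_cluster", list(min_size = min_size)),
      graph_node("update", "set_attribute", list(name = "current_label")),
      graph_node("save", "set_attribute", list(name = "cluster_label"))),
    connections = list(
      connection("pos", "positions", "nbr", "positions"),
      connection("nbr", "edges", "grp", "edges"),
      connection("prev", "value", "track", "prev"),
      connection("grp", "labels", "track", "groups"),
      connection("track", "labels", "update", "value"),
      connection("track", "labels", "save", "value")),
    attributes = list(
      attr_decl("current_label", init = init, record = TRUE),
      attr_decl("cluster_label", record = TRUE)),
    direction = direction)
}

#' Colour-graduation graph
#'
#' Reads a per-frame label attribute (named by `label_attr`; typically
#' imported into the trajectory frames or produced by a tracking run) and
#' fades each atom's colour toward red while labelled and toward blue while
#' not, accumulating in the recorded `color` attribute. Running the same
#' graph forward and backward and max-combining the two colour histories
#' grades atoms by how near in time they are to cluster membership.
#'
#' @param fade_rate Colour step per frame, in (0, 1].
#' @param label_attr Name of the per-atom label attribute to read.
#' @param direction Execution direction.
#' @return An [md_graph()].
#' @export
color_graph <- function(fade_rate = 0.05, label_attr = "cluster_label",
                        direction = "forward") {
  md_graph(
    nodes = list(
      graph_node("labels", "get_attribute", list(name = label_attr)),
      graph_node("prev", "get_attribute", list(name = "color")),
      graph_node("fade", "labels2colors", list(fade_rate = fade_rate)),
      graph_node("update", "set_attribute", list(name = "color"))),
    connections = list(
      connection("labels", "value", "fade", "labels"),
      connection("prev", "value", "fade", "colors"),
      connection("fade", "colors", "update", "value")),
    attributes = list(attr_decl("color", init = 0, record = TRUE)),
    direction = direction)
}

#' MCG-1 hydrate-recognition graph
#'
#' The full mutually-coordinated-guest pipeline: guest pairs within
#' `cutoff`, coordinated waters in the double cone, hydrogen bonds among
#' them, O-H bonds reconnected to O-O edges, pentagonal rings, and
#' labelling of caged guests plus their cage oxygens. The labels are saved
#' as the recorded `mcg_label` attribute; the number of classified
#' molecules feeds an accumulating plot node (`order_param`); the O-O
#' edges drive the extra-bonds node and the labels the visibility range.
#'
#' @param guests Selection string for guest atoms (e.g. `"resname=MET"`).
#' @param waters Selection string for water residues.
#' @param cutoff Guest-pair cutoff, angstrom.
#' @param cone_angle Coordination cone half-angle, degrees.
#' @param d_oo_max,angle_max Hydrogen-bond criteria (angstrom, degrees).
#' @param n Ring size.
#' @param min_rings Minimum rings for a mutually coordinated pair.
#' @return An [md_graph()].
#' @export
mcg_graph <- function(guests = "resname=MET", waters = "resname=SOL|HOH|WAT",
                      cutoff = 9.0, cone_angle = 45, d_oo_max = 3.5,
                      angle_max = 30, n = 5, min_rings = 1) {
  md_graph(
    nodes = list(
      graph_node("guests", "filter_guests",
                 list(guests = guests, cutoff = cutoff)),
      graph_node("waters", "filter_waters",
                 list(waters = waters, cone_angle = cone_angle)),
      graph_node("hbonds", "hbonds_filtered",
                 list(d_oo_max = d_oo_max, angle_max = angle_max)),
      graph_node("oo", "reconnect_water"),
      graph_node("rings", "find_links", list(n = n)),
      graph_node("hydrate", "register_hydrate", list(min_rings = min_rings)),
      graph_node("save", "set_attribute", list(name = "mcg_label")),
      graph_node("count", "classified_count"),
      graph_node("order_param", "plot_data"),
      graph_node("bonds", "extra_bonds"),
      graph_node("range", "show_range", list(lo = 0.5, hi = Inf))),
    connections = list(
      connection("guests", "pairs", "waters", "pairs"),
      connection("waters", "selected", "hbonds", "selected"),
      connection("hbonds", "hbonds", "oo", "hbonds"),
      connection("oo", "edges", "rings", "edges"),
      connection("guests", "pairs", "hydrate", "pairs"),
      connection("waters", "pair_waters", "hydrate", "pair_waters"),
      connection("rings", "rings", "hydrate", "rings"),
      connection("hydrate", "labels", "save", "value"),
      connection("hydrate", "labels", "count", "labels"),
      connection("count", "count", "order_param", "y"),
      connection("oo", "edges", "bonds", "pairs"),
      connection("hydrate", "labels", "range", "values")),
    attributes = list(attr_decl("mcg_label", record = TRUE)))
}
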