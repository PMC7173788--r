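.onLoad <- function(libname, pkgname) {
  register_builtin_readers()
  register_builtin_node_kinds()
  register_script_kind()
  register_cluster_node_kinds()
  register_hydrate_node_kinds()
}
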