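# Keyword ensembles scanned for inside extracted tables and body text.
# Patterns use the '\W...\W' whole-word convention; '|' is alternation.
# Compiled boundary-safe (string start/end count as boundaries), case-insensitive.
matrix:
  - '\Wmilk\W'
  - '\Whoney.?\W'
  - '\Wserum\W|\WSera\W'
  - '\Wtissue.?\W'
  - '\Wkidney\W'
  - '\Wdairy\W'
  - '\Waquaculture\W'
  - '\Wurine\W'
desired_field:
  - '\Wsafety\W'
  - '\Wconcentration for positive ppb\W'
  - '\Wcharmsl\W'
  - '\Wsensitivity\W'
  - '\Wtest sensitivity\W'
  - '\Wconcentration\W'
  - '\Wpositive concentration\W'
  - '\Wdetection level\W'
  - '\Wdetection range\W'
unit:
  - '\Wppb\W'
  - '\Wppm\W'
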