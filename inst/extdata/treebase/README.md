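Place the deposited nuclear and plastid NEXUS matrices here as
`nuclear.nex` and `plastid.nex` (they are not redistributed with the
package) and reinstall; the acceptance test will then verify their
published dimensions and parsimony-informative site counts.
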