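alias	canonical
busereline	buserelin
buserelina	buserelin
gosereline	goserelin
goserelina	goserelin
histreline	histrelin
histrelina	histrelin
leuproreline	leuprorelin
leuprorelina	leuprorelin
leuprolide	leuprorelin
triptoreline	triptorelin
triptorelina	triptorelin
nafareline	nafarelin
nafarelina	nafarelin
bicalutamida	bicalutamide
flutamida	flutamide
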