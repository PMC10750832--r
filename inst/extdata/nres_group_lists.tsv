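treatment	group	variety
0	HYHN	CP02-F10
0	HYHN	CP02-1
0	HYHN	CP02-2
0	HYHN	AK58
0	HYHN	DM1301
0	HYHN	GH9
0	HYHN	KN9204
0	HYHN	PM108
0	HYHN	SX6
0	HYHN	WY2
0	HYHN	WM108
0	HYHN	WM52
0	HYHN	YFM5
0	HYHN	YFM8
0	HYHN	YM16
0	HYHN	YM25
0	HYHN	ZM9523
0	HYHN	ZM12
0	HYHN	ZM168
0	HYHN	ZM4
0	HYHN	ZM5
0	HYHN	ZM8
180	HYHN	CP02-1
180	HYHN	P124
180	HYHN	BJ0601
180	HYHN	HM6
180	HYHN	LY098
180	HYHN	NN06Y86
180	HYHN	SX6
180	HYHN	SM3
180	HYHN	SM8
180	HYHN	TM108
180	HYHN	WM108
180	HYHN	XM32
180	HYHN	YFM6
180	HYHN	YM20
180	HYHN	ZM9523
180	HYHN	ZM09196
180	HYHN	ZM12
180	HYHN	ZM168
180	HYHN	ZM4
180	HYHN	ZM5
180	HYHN	ZM8
270	HYHN	CP01-204
270	HYHN	CP01-4
270	HYHN	CP02-F10
270	HYHN	CP02-1
270	HYHN	CP02-6-1
270	HYHN	CP20-2
270	HYHN	P124
270	HYHN	BJ0601
270	HYHN	HM6
270	HYHN	KN9204
270	HYHN	WM108
270	HYHN	XM32
270	HYHN	YM25
270	HYHN	ZM9523
270	HYHN	ZM10
270	HYHN	ZM168
270	HYHN	ZM5
270	HYHN	ZM8
0	LYLN	CP01-3
0	LYLN	CP01-204
0	LYLN	CP01-4
0	LYLN	CP02-6-1
0	LYLN	CP20-1
0	LYLN	P14
0	LYLN	HM30
0	LYLN	LY098
0	LYLN	NN06Y86
0	LYLN	NM13
0	LYLN	NM26
0	LYLN	NMZ1019
0	LYLN	NZM1
0	LYLN	SM3
0	LYLN	SM8
0	LYLN	SM553
0	LYLN	WL1216
0	LYLN	XM32
0	LYLN	YFM6
0	LYLN	YM158
0	LYLN	YM20
0	LYLN	ZM11
180	LYLN	CP01-3
180	LYLN	CP01-4
180	LYLN	CP02-21
180	LYLN	CP02-6-1
180	LYLN	CP03-1
180	LYLN	CP20-1
180	LYLN	AK58
180	LYLN	HM30
180	LYLN	NM13
180	LYLN	NMZ1019
180	LYLN	NZM1
180	LYLN	SKM1
180	LYLN	SM553
180	LYLN	WM52
180	LYLN	WL1216
180	LYLN	YFM5
180	LYLN	YM158
180	LYLN	ZM10
270	LYLN	CP01-3
270	LYLN	AK58
270	LYLN	HM30
270	LYLN	LY098
270	LYLN	NN06Y86
270	LYLN	NM26
270	LYLN	NMZ1019
270	LYLN	PM108
270	LYLN	SKM1
270	LYLN	SM553
270	LYLN	WY2
270	LYLN	WM52
270	LYLN	WL1216
270	LYLN	YFM6
270	LYLN	YFM8
270	LYLN	ZM09196
270	LYLN	ZM11
270	LYLN	ZM4
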